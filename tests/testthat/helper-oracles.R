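# Independent oracles and small fixtures shared across the test files. Each
# oracle is coded directly from first principles, separate from the package
# implementation it checks.

# All permutations of a vector (used for exhaustive open-tour enumeration).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exhaustive optimal open-tour cost with a fixed first point.
brute_force_open_tour <- function(points, base_index = 1L) {
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  rest <- setdiff(seq_len(n), base_index)
  costs <- vapply(all_permutations(rest), function(p) {
    o <- c(base_index, p)
    sum(dmat[cbind(o[-n], o[-1L])])
  }, numeric(1))
  min(costs)
}

# Sinuosity of a plane sinusoid y = A sin(2 pi x / lambda) over [0, L] by
# dense trapezoid quadrature of sqrt(1 + y'^2).
quadrature_sinuosity <- function(amplitude, wavelength, axial_length,
                                 n = 200001) {
  x <- seq(0, axial_length, length.out = n)
  dy <- amplitude * 2 * pi / wavelength * cos(2 * pi * x / wavelength)
  f <- sqrt(1 + dy^2)
  arc <- sum((f[-1] + f[-n]) / 2 * diff(x))
  100 * arc / axial_length
}

# Consequence oracle: rebuild the full mutant CDS, translate reference and
# mutant proteins, and classify from the protein difference.
translate_cds_oracle <- function(rec, models, genome) {
  span <- rec$pos + nchar(rec$ref) - 1L
  hit <- models[models$seqid == rec$chrom & models$start <= span &
                  models$end >= rec$pos, , drop = FALSE]
  if (!nrow(hit)) return("noncoding")
  g <- hit$gene_id[1L]
  ex <- models[models$gene_id == g, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nchar(rec$ref) != nchar(rec$alt)) {
    if (rec$pos < hit$start[1L] || span > hit$end[1L]) return("splice_region")
    return(if (abs(nchar(rec$ref) - nchar(rec$alt)) %% 3L == 0L) {
      "inframe_indel"
    } else {
      "frameshift_indel"
    })
  }
  chrseq <- as.character(genome[[rec$chrom]])
  stopifnot(substr(chrseq, rec$pos, rec$pos) == rec$ref)
  mut <- chrseq
  substr(mut, rec$pos, rec$pos) <- rec$alt
  splice <- function(s) {
    paste(vapply(seq_len(nrow(ex)),
                 function(j) substr(s, ex$start[j], ex$end[j]), character(1)),
          collapse = "")
  }
  cds_r <- Biostrings::DNAString(splice(chrseq))
  cds_a <- Biostrings::DNAString(splice(mut))
  if (ex$strand[1L] == "-") {
    cds_r <- Biostrings::reverseComplement(cds_r)
    cds_a <- Biostrings::reverseComplement(cds_a)
  }
  pr <- as.character(Biostrings::translate(cds_r, no.init.codon = TRUE))
  pa <- as.character(Biostrings::translate(cds_a, no.init.codon = TRUE))
  if (pr == pa) return("synonymous")
  d <- which(strsplit(pr, "")[[1]] != strsplit(pa, "")[[1]])[1L]
  if (substr(pa, d, d) == "*" && substr(pr, d, d) != "*") "nonsense" else "missense"
}

# Draw random variants over a simulated genome, mixing coding SNVs, indels
# and intergenic positions.
random_variants <- function(models, genome, n, seed) {
  set.seed(seed)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    if (runif(1) < 0.6) {
      row <- models[sample(nrow(models), 1L), ]
      pos <- sample(row$start:row$end, 1L)
      chrom <- row$seqid
    } else {
      chrom <- sample(names(genome), 1L)
      pos <- sample(1000:19000, 1L)
    }
    if (runif(1) < 0.15) {
      len <- sample(1:4, 1L)
      ref <- substr(as.character(genome[[chrom]]), pos, pos + len)
      alt <- substr(ref, 1L, 1L)
    } else {
      ref <- substr(as.character(genome[[chrom]]), pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    }
    recs[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

# Fast small tube fixtures for unit tests.
small_straight_tube <- function(length = 40, radius = 3, noise_sd = 0, seed = 1L) {
  render_tube_stack(tube_render_spec(
    centerline_spec("straight", length = length), radius = radius,
    voxel_size = c(0.5, 0.5, 1), noise_sd = noise_sd, seed = seed))
}

# Benchmark geometries used by both the unit and acceptance suites: thin
# tubes (radius small against the bend scale) so that per-slice centroids
# track the centerline.
bench_sinusoid_spec <- function(noise_sd = 0, seed = 1L) {
  tube_render_spec(
    centerline_spec("sinusoid", length = 150, amplitude = 10, wavelength = 50),
    radius = 4, voxel_size = c(0.4, 0.4, 1.2), noise_sd = noise_sd, seed = seed)
}

bench_semicircle_spec <- function() {
  tube_render_spec(centerline_semicircle(40), radius = 4,
                   voxel_size = c(0.4, 0.4, 0.8),
                   orientation = c(x = "y", y = "z", z = "x"))
}

# Sinusoid amplitude whose true sinuosity is `target` (percent) at the given
# wavelength and axial length, solved on the quadrature oracle.
amplitude_for_sinuosity <- function(target, wavelength = 100, axial_length = 150) {
  if (target <= 100) return(0)
  uniroot(function(A) quadrature_sinuosity(A, wavelength, axial_length) - target,
          c(0, 60))$root
}
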