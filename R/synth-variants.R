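# Synthetic variant tables with generation-time truth labels, synthetic gene
# models, and the VCF/GFF3/FASTA interchange helpers.

#' Specify a synthetic variant table
#'
#' Each predicate of the filter cascade passes independently with the given
#' fraction; field values are then drawn consistently with the outcome, and
#' boundary values (quality exactly at the threshold, depth at the cap and one
#' above, support at the threshold and one above, AF1 exactly at its cutoff)
#' occur with positive probability on both sides. The truth label of each
#' record -- whether it survives the whole record-level cascade -- is computed
#' at generation time by direct predicate application, independently of the
#' filter functions.
#'
#' @param n_records number of records.
#' @param pass_fractions named list of per-predicate pass probabilities with
#'   entries `quality`, `coverage`, `support`, `homozygous`, `private`,
#'   `uv_signature`.
#' @param missing_genotype_fraction fraction of records missing both FQ and
#'   AF1 (these cannot establish homozygosity and must fail).
#' @param seed RNG seed.
#' @return An object of class `synthetic_variant_spec`.
#' @export
synthetic_variant_spec <- function(n_records = 200,
                                   pass_fractions = list(quality = 0.75,
                                                         coverage = 0.75,
                                                         support = 0.75,
                                                         homozygous = 0.7,
                                                         private = 0.85,
                                                         uv_signature = 0.6),
                                   missing_genotype_fraction = 0.03,
                                   seed = 1L) {
  need <- c("quality", "coverage", "support", "homozygous", "private", "uv_signature")
  assert_that(n_records >= 1, "n_records must be >= 1")
  assert_that(all(need %in% names(pass_fractions)),
              "pass_fractions must name all six predicates")
  p <- unlist(pass_fractions[need])
  assert_that(all(p >= 0 & p <= 1), "pass fractions must be in [0, 1]")
  structure(list(n_records = as.integer(n_records),
                 pass_fractions = as.list(p),
                 missing_genotype_fraction = missing_genotype_fraction,
                 seed = seed),
            class = "synthetic_variant_spec")
}

#' Generate a synthetic variant table with known truth labels
#'
#' @param spec a [synthetic_variant_spec()].
#' @return An object of class `synthetic_variant_table`: list with `records`
#'   (a variant record table), `comparison_sets` (one table of planted
#'   non-private variants), and `truth` (logical: survives the record-level
#'   cascade), computed at generation time by independent predicate
#'   application.
#' @export
make_variant_table <- function(spec) {
  assert_that(inherits(spec, "synthetic_variant_spec"),
              "spec must be a synthetic_variant_spec")
  n <- spec$n_records
  p <- spec$pass_fractions
  with_seed(spec$seed, {
    pass_q <- runif(n) < p$quality
    pass_cov <- runif(n) < p$coverage
    pass_sup <- runif(n) < p$support
    pass_hom <- runif(n) < p$homozygous
    pass_priv <- runif(n) < p$private
    pass_uv <- runif(n) < p$uv_signature
    missing_gt <- runif(n) < spec$missing_genotype_fraction
    pass_hom[missing_gt] <- FALSE

    qual <- ifelse(pass_q, sample(c(36:80), n, replace = TRUE),
                   sample(c(10:35, 35), n, replace = TRUE))
    dp <- ifelse(pass_cov, sample(c(20:100, 100), n, replace = TRUE),
                 sample(c(101, 101:220), n, replace = TRUE))
    alt_support <- ifelse(pass_sup,
                          pmin(dp, sample(c(8, 8:20), n, replace = TRUE)),
                          sample(c(0:7, 7), n, replace = TRUE))
    fq <- numeric(n); af1 <- numeric(n)
    hom_via_fq <- runif(n) < 0.5
    fq[pass_hom & hom_via_fq] <- runif(sum(pass_hom & hom_via_fq), -80, -0.5)
    af1[pass_hom & hom_via_fq] <- runif(sum(pass_hom & hom_via_fq), 0, 0.5)
    fq[pass_hom & !hom_via_fq] <- runif(sum(pass_hom & !hom_via_fq), 0.5, 40)
    af1[pass_hom & !hom_via_fq] <- runif(sum(pass_hom & !hom_via_fq), 0.5002, 1)
    fq[!pass_hom] <- runif(sum(!pass_hom), 0.5, 40)
    af1[!pass_hom] <- sample(c(0.5001, round(runif(sum(!pass_hom), 0, 0.5), 4)),
                             sum(!pass_hom), replace = TRUE)
    fq[missing_gt] <- NA_real_
    af1[missing_gt] <- NA_real_

    # plant one record on each side of every predicate boundary so the
    # cascade's strict/non-strict comparisons are always exercised
    plant <- function(pool, expr) {
      idx <- which(pool)
      if (length(idx)) expr(idx[1L])
      invisible(NULL)
    }
    plant(!pass_q, function(i) qual[i] <<- 35)
    plant(pass_q, function(i) qual[i] <<- 36)
    plant(pass_cov, function(i) dp[i] <<- 100L)
    plant(!pass_cov, function(i) dp[i] <<- 101L)
    plant(pass_sup & dp >= 8, function(i) alt_support[i] <<- 8L)
    plant(!pass_sup, function(i) alt_support[i] <<- 7L)
    plant(!pass_hom & !missing_gt, function(i) {
      fq[i] <<- 10; af1[i] <<- 0.5001
    })

    bases <- c("A", "C", "G", "T")
    ref <- character(n); alt <- character(n)
    indel <- logical(n)
    for (i in seq_len(n)) {
      if (pass_uv[i]) {
        pick <- sample(3L, 1L)
        if (pick == 1L) {
          ref[i] <- "G"; alt[i] <- "A"
        } else if (pick == 2L) {
          ref[i] <- "C"; alt[i] <- "T"
        } else {
          indel[i] <- TRUE
          if (runif(1) < 0.5) {
            ref[i] <- paste(sample(bases, sample(2:4, 1L), replace = TRUE), collapse = "")
            alt[i] <- substr(ref[i], 1L, 1L)
          } else {
            alt[i] <- paste(sample(bases, sample(2:4, 1L), replace = TRUE), collapse = "")
            ref[i] <- substr(alt[i], 1L, 1L)
          }
        }
      } else {
        repeat {
          ref[i] <- sample(bases, 1L)
          alt[i] <- sample(setdiff(bases, ref[i]), 1L)
          if (!((ref[i] == "G" && alt[i] == "A") || (ref[i] == "C" && alt[i] == "T"))) break
        }
      }
    }

    records <- data.frame(
      chrom = paste0("scaffold_", sample(1:8, n, replace = TRUE)),
      pos = sample(1:5e5, n, replace = FALSE),
      ref = ref, alt = alt, qual = as.numeric(qual),
      dp = as.integer(dp), alt_support = as.integer(alt_support),
      fq = fq, af1 = af1, line_id = "focal",
      stringsAsFactors = FALSE)
    records$dp4 <- paste(pmax(records$dp - records$alt_support, 0L) %/% 2L,
                         pmax(records$dp - records$alt_support, 0L) -
                           pmax(records$dp - records$alt_support, 0L) %/% 2L,
                         records$alt_support %/% 2L,
                         records$alt_support - records$alt_support %/% 2L,
                         sep = ",")

    planted <- records[!pass_priv, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    decoys <- data.frame(
      chrom = paste0("scaffold_", sample(1:8, 40, replace = TRUE)),
      pos = sample(5e5 + (1:1e5), 40), ref = sample(bases, 40, replace = TRUE),
      alt = sample(bases, 40, replace = TRUE), stringsAsFactors = FALSE)
    comparison <- rbind(planted, decoys)
    comparison <- comparison[sample(nrow(comparison)), , drop = FALSE]
    comparison$line_id <- "non_allelic_1"
    rownames(comparison) <- NULL

    # generation-time truth: direct predicate application, coded independently
    # of the filter functions
    truth <- (qual > 35) & (dp <= 100) & (alt_support > 7) &
      ((!is.na(fq) & fq < 0) | (!is.na(af1) & af1 > 0.5001)) &
      pass_priv &
      (indel | (ref == "G" & alt == "A") | (ref == "C" & alt == "T"))

    structure(list(records = records, comparison_sets = list(comparison),
                   truth = unname(truth), spec = spec),
              class = "synthetic_variant_table")
  })
}

#' Simulate a genome with multi-exon, mixed-strand gene models
#'
#' Builds a random genome and a set of gene models whose coding sequences are
#' split over one to `max_exons` exons on either strand, with total CDS
#' length a multiple of three -- the substrate for validating the consequence
#' caller against a translate-the-whole-CDS oracle.
#'
#' @param n_genes number of genes.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length in bp.
#' @param max_exons maximum exons per gene.
#' @param seed RNG seed.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and `models`
#'   (data frame: seqid, start, end, strand, gene_id, exon_rank).
#' @export
simulate_gene_models <- function(n_genes = 12, n_scaffolds = 2,
                                 scaffold_length = 20000, max_exons = 4,
                                 seed = 1L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    genome <- Biostrings::DNAStringSet(vapply(seq_len(n_scaffolds), function(i) {
      paste(sample(bases, scaffold_length, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- paste0("scaffold_", seq_len(n_scaffolds))
    rows <- list()
    per_scaffold <- split(seq_len(n_genes),
                          rep(seq_len(n_scaffolds), length.out = n_genes))
    for (sc in seq_len(n_scaffolds)) {
      cursor <- 200L
      for (g in per_scaffold[[sc]]) {
        n_ex <- sample(seq_len(max_exons), 1L)
        ex_len <- sample(30:180, n_ex, replace = TRUE)
        total <- sum(ex_len)
        ex_len[n_ex] <- ex_len[n_ex] + (3L - total %% 3L) %% 3L
        gaps <- sample(50:300, n_ex, replace = TRUE)
        strand <- sample(c("+", "-"), 1L)
        starts <- integer(n_ex); ends <- integer(n_ex)
        for (e in seq_len(n_ex)) {
          starts[e] <- cursor + gaps[e]
          ends[e] <- starts[e] + ex_len[e] - 1L
          cursor <- ends[e]
        }
        cursor <- cursor + 400L
        if (max(ends) > scaffold_length - 200L) next
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = paste0("scaffold_", sc), start = starts, end = ends,
          strand = strand, gene_id = sprintf("gene_%02d", g),
          exon_rank = if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex)),
          stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, models = do.call(rbind, rows))
  })
}

#' Write a variant record table as a VCF file
#'
#' Emits a minimal VCF 4.2 file with the legacy pileup-caller INFO keys DP,
#' DP4, FQ and AF1, one line per record.
#'
#' @param records a variant record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, path) {
  validate_records(records)
  info <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    parts <- c(sprintf("DP=%d", as.integer(r$dp)))
    if (!is.null(r$dp4)) parts <- c(parts, sprintf("DP4=%s", r$dp4))
    if (!is.null(r$fq) && !is.na(r$fq)) parts <- c(parts, sprintf("FQ=%g", r$fq))
    if (!is.null(r$af1) && !is.na(r$af1)) parts <- c(parts, sprintf("AF1=%g", r$af1))
    paste(parts, collapse = ";")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rhizotrace",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref-forward, ref-reverse, alt-forward and alt-reverse read counts\">",
    "##INFO=<ID=FQ,Number=1,Type=Float,Description=\"Consensus quality; negative when the site looks homozygous\">",
    "##INFO=<ID=AF1,Number=1,Type=Float,Description=\"Estimated first alternate allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                format(records$qual, trim = TRUE), "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant record table from a VCF file
#'
#' Parses a VCF (plain or bgzipped) with the legacy pileup-caller INFO keys
#' DP, DP4, FQ and AF1. Alternate support is taken as the sum of the
#' alternate-forward and alternate-reverse DP4 counts.
#'
#' @param path VCF path.
#' @param line_id optional line identifier stored on every record.
#' @return A variant record table (see [variant_records]).
#' @export
read_variant_vcf <- function(path, line_id = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  dp4 <- vcfR::extract.info(vcf, "DP4")
  fq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "FQ")))
  af1 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF1")))
  alt_support <- vapply(dp4, function(s) {
    if (is.na(s)) return(NA_integer_)
    v <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    if (length(v) != 4L) return(NA_integer_)
    v[3L] + v[4L]
  }, integer(1), USE.NAMES = FALSE)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
             dp = dp, alt_support = alt_support, fq = fq, af1 = af1,
             dp4 = unname(dp4), line_id = line_id, stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' One `gene` feature plus one `CDS` row per exon, with phase computed from
#' the cumulative coding length in transcription order.
#'
#' @param models a gene-model table (see [simulate_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in unique(models$gene_id)) {
    ex <- models[models$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$exon_rank %||% seq_len(nrow(ex))), , drop = FALSE]
    strand <- ex$strand[1L]
    lines <- c(lines, paste(ex$seqid[1L], "rhizotrace", "gene", min(ex$start),
                            max(ex$end), ".", strand, ".",
                            sprintf("ID=%s", g), sep = "\t"))
    phase <- 0L
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$seqid[e], "rhizotrace", "CDS", ex$start[e],
                              ex$end[e], ".", strand, phase,
                              sprintf("ID=%s.cds%d;Parent=%s", g, e, g), sep = "\t"))
      phase <- (3L - ((ex$end[e] - ex$start[e] + 1L - phase) %% 3L)) %% 3L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports the CDS features of a GFF3 file into the flat gene-model table the
#' consequence caller consumes, using the `Parent` (or `ID`) attribute as the
#' gene identifier.
#'
#' @param path GFF3 path.
#' @return A gene-model table: seqid, start, end, strand, gene_id, exon_rank.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_config("read_gene_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  gene_id <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) sub("\\.cds\\d+$", "", p[[1]]) else NA_character_,
           character(1))
  } else {
    sub("\\.cds\\d+$", "", df$ID)
  }
  out <- data.frame(seqid = as.character(df$seqnames), start = df$start,
                    end = df$end, strand = as.character(df$strand),
                    gene_id = gene_id, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  ranks <- unlist(lapply(split(out$strand, out$gene_id), function(s) {
    if (s[1L] == "+") seq_along(s) else rev(seq_along(s))
  }), use.names = FALSE)
  out$exon_rank <- ranks
  rownames(out) <- NULL
  out
}
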