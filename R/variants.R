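# Candidate-variant discovery cascade for UV-B mutagenesis screens: quality,
# coverage, support and homozygosity filters, privacy against non-allelic
# lines, the UV mutation signature, and coding-consequence annotation.

#' Variant record table
#'
#' Variant records are plain data frames with one row per mismatch call and
#' columns `chrom`, `pos` (1-based), `ref`, `alt`, `qual` (site quality),
#' `dp` (read depth), `alt_support` (reads supporting the alternate allele,
#' the sum of the forward and reverse alternate counts), `fq`, `af1` and
#' optionally `line_id` and `dp4`. [read_variant_vcf()] builds such tables
#' from VCF files carrying the legacy pileup-caller INFO keys DP, DP4, FQ and
#' AF1.
#'
#' @name variant_records
NULL

validate_records <- function(records) {
  need <- c("chrom", "pos", "ref", "alt")
  assert_that(is.data.frame(records) && all(need %in% names(records)),
              "records must be a data frame with chrom, pos, ref, alt columns")
  records
}

#' Filter on site quality
#'
#' Keeps records with quality strictly higher than `q_min` (a call at exactly
#' the threshold is dropped). Records with missing quality are dropped.
#'
#' @param records a variant record table.
#' @param q_min quality threshold (default 35).
#' @return The surviving records.
#' @export
filter_quality <- function(records, q_min = 35) {
  validate_records(records)
  records[!is.na(records$qual) & records$qual > q_min, , drop = FALSE]
}

#' Filter on read coverage
#'
#' Excludes records in regions with coverage exceeding `cov_max` reads:
#' exactly `cov_max` is kept, `cov_max + 1` is dropped. High-coverage regions
#' are typically collapsed repeats where mismatch calls are unreliable.
#'
#' @param records a variant record table.
#' @param cov_max depth cap (default 100).
#' @return The surviving records.
#' @export
filter_coverage <- function(records, cov_max = 100) {
  validate_records(records)
  records[!is.na(records$dp) & records$dp <= cov_max, , drop = FALSE]
}

#' Filter on alternate-allele support
#'
#' Keeps records supported by strictly more than `min_reads` alternate-allele
#' reads (exactly `min_reads` is dropped).
#'
#' @param records a variant record table.
#' @param min_reads support threshold (default 7).
#' @return The surviving records.
#' @export
filter_support <- function(records, min_reads = 7) {
  validate_records(records)
  records[!is.na(records$alt_support) & records$alt_support > min_reads, , drop = FALSE]
}

#' Filter on homozygosity evidence
#'
#' Keeps records that look sufficiently homozygous: a negative FQ value or an
#' AF1 value strictly higher than 0.5001. Records missing both fields cannot
#' establish homozygosity and are dropped with a warning.
#'
#' @param records a variant record table.
#' @param af1_min AF1 threshold (default 0.5001, strict).
#' @return The surviving records.
#' @export
filter_homozygous <- function(records, af1_min = 0.5001) {
  validate_records(records)
  fq <- if ("fq" %in% names(records)) records$fq else rep(NA_real_, nrow(records))
  af1 <- if ("af1" %in% names(records)) records$af1 else rep(NA_real_, nrow(records))
  both_missing <- is.na(fq) & is.na(af1)
  if (any(both_missing)) {
    warning(sprintf("%d record(s) missing both FQ and AF1 were dropped", sum(both_missing)),
            call. = FALSE)
  }
  keep <- (!is.na(fq) & fq < 0) | (!is.na(af1) & af1 > af1_min)
  records[keep, , drop = FALSE]
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = "\r")
}

#' Keep variants private to the focal line
#'
#' Drops any record whose (chrom, pos, ref, alt) key appears in any of the
#' comparison sets -- the variant tables of other, non-allelic sequenced lines
#' and of the wild-type accessions. Matching requires the identical alternate
#' allele, not just the position.
#'
#' @param records a variant record table.
#' @param comparison_sets list of variant record tables (possibly empty).
#' @return The surviving records.
#' @export
filter_private <- function(records, comparison_sets = list()) {
  validate_records(records)
  if (!length(comparison_sets)) return(records)
  seen <- unlist(lapply(comparison_sets, function(s) variant_key(validate_records(s))))
  records[!(variant_key(records) %in% seen), , drop = FALSE]
}

is_snv <- function(records) {
  nchar(records$ref) == 1L & nchar(records$alt) == 1L
}

#' Filter on the UV-B mutation signature
#'
#' UV-B lesions predominantly produce G-to-A and C-to-T substitutions (one
#' event read on either strand) and small indels. Keeps SNVs whose recorded
#' ref/alt pair is G>A or C>T, and all indels.
#'
#' @param records a variant record table.
#' @return The surviving records.
#' @export
filter_uv_signature <- function(records) {
  validate_records(records)
  snv <- is_snv(records)
  keep <- (!snv) |
    (records$ref == "G" & records$alt == "A") |
    (records$ref == "C" & records$alt == "T")
  records[keep, , drop = FALSE]
}

#' Annotate coding consequences of variants
#'
#' Maps each variant onto the coding sequences of a set of gene models and
#' classifies it: `nonsense` (the alternate codon is a stop where the
#' reference codon is not), `missense`, `synonymous`, `frameshift_indel`
#' (length change not a multiple of three), `inframe_indel`, `splice_region`
#' (an indel overlapping an exon boundary) or `noncoding`. Minus-strand genes
#' are handled by complementing the alleles and positioning within the
#' reverse-complemented spliced CDS; codons are translated with the standard
#' genetic code.
#'
#' @param records a variant record table.
#' @param models a gene-model table: one row per CDS exon with columns
#'   `seqid`, `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`) and
#'   `gene_id` (see [read_gene_models()] / [simulate_gene_models()]).
#' @param genome a [Biostrings::DNAStringSet] whose names match `seqid`.
#' @return A data frame with one row per record: `gene_id`, `consequence`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
annotate_consequence <- function(records, models, genome) {
  validate_records(records)
  assert_that(all(c("seqid", "start", "end", "strand", "gene_id") %in% names(models)),
              "models must have seqid, start, end, strand, gene_id columns")
  bad_len <- tapply(models$end - models$start + 1L, models$gene_id, sum) %% 3L != 0L
  if (any(bad_len)) {
    warning(sprintf("CDS length not divisible by 3 for gene(s): %s",
                    paste(names(bad_len)[bad_len], collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(gene_id = NA_character_, consequence = "noncoding",
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, nrow(records)), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(records)) return(out[0L, , drop = FALSE])
  for (i in seq_len(nrow(records))) {
    out[i, ] <- classify_one_variant(records[i, , drop = FALSE], models, genome)
  }
  out
}

classify_one_variant <- function(rec, models, genome) {
  ref <- rec$ref; alt <- rec$alt
  span <- rec$pos + nchar(ref) - 1L
  hit <- models[models$seqid == rec$chrom & models$start <= span & models$end >= rec$pos, ,
                drop = FALSE]
  none <- list(gene_id = NA_character_, consequence = "noncoding",
               ref_codon = NA_character_, alt_codon = NA_character_,
               ref_aa = NA_character_, alt_aa = NA_character_)
  if (!nrow(hit)) return(none)
  gene <- hit$gene_id[1L]
  exons <- models[models$gene_id == gene, , drop = FALSE]
  exons <- exons[order(exons$start), , drop = FALSE]
  res <- none
  res$gene_id <- gene

  if (nchar(ref) != nchar(alt)) {
    exon <- hit[1L, ]
    if (rec$pos < exon$start || span > exon$end) {
      res$consequence <- "splice_region"
    } else if ((abs(nchar(ref) - nchar(alt)) %% 3L) == 0L) {
      res$consequence <- "inframe_indel"
    } else {
      res$consequence <- "frameshift_indel"
    }
    return(res)
  }

  # SNV: locate within the spliced CDS
  strand <- exons$strand[1L]
  widths <- exons$end - exons$start + 1L
  before <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  k <- which(exons$start <= rec$pos & exons$end >= rec$pos)[1L]
  cat_pos <- before[k] + (rec$pos - exons$start[k] + 1L)
  cds_fwd <- paste(vapply(seq_len(nrow(exons)), function(j) {
    as.character(Biostrings::subseq(genome[[exons$seqid[j]]],
                                    exons$start[j], exons$end[j]))
  }, character(1)), collapse = "")
  L <- nchar(cds_fwd)
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_fwd)))
    cds_pos <- L - cat_pos + 1L
    ref_c <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    alt_c <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  } else {
    cds <- cds_fwd
    cds_pos <- cat_pos
    ref_c <- ref
    alt_c <- alt
  }
  if (cds_pos > 3L * (L %/% 3L)) return(res)  # trailing partial codon
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  within <- cds_pos - 3L * (codon_idx - 1L)
  ref_codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  if (substr(ref_codon, within, within) != ref_c) {
    warning(sprintf("reference allele mismatch at %s:%d", rec$chrom, rec$pos),
            call. = FALSE)
  }
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  code <- Biostrings::GENETIC_CODE
  res$ref_codon <- ref_codon
  res$alt_codon <- alt_codon
  res$ref_aa <- unname(code[ref_codon])
  res$alt_aa <- unname(code[alt_codon])
  res$consequence <- if (res$alt_aa == res$ref_aa) {
    "synonymous"
  } else if (res$alt_aa == "*" && res$ref_aa != "*") {
    "nonsense"
  } else {
    "missense"
  }
  res
}

AMINO_ACID_CHANGING <- c("nonsense", "missense", "frameshift_indel", "inframe_indel")

#' Run the full candidate-variant filter cascade
#'
#' Applies the stages in order -- quality, coverage, support, homozygosity,
#' privacy against comparison lines, UV signature and (when gene models are
#' supplied) coding consequence -- recording the record count entering and
#' leaving each stage. Candidates are the survivors whose consequence changes
#' the predicted amino-acid sequence (`nonsense`, `missense`,
#' `frameshift_indel`, `inframe_indel`).
#'
#' @param records a variant record table.
#' @param comparison_sets list of variant tables from non-allelic lines and
#'   wild-type accessions.
#' @param models,genome optional gene models and genome for consequence
#'   annotation; when omitted the cascade stops after the UV-signature stage
#'   and candidates are the record-level survivors.
#' @param q_min,cov_max,min_reads,af1_min stage thresholds.
#' @return An object of class `cascade_report`: list with `counts` (data
#'   frame stage/n_in/n_out), `survivors` (record-level survivors, annotated
#'   when models are given) and `candidates`.
#' @export
run_cascade <- function(records, comparison_sets = list(), models = NULL,
                        genome = NULL, q_min = 35, cov_max = 100,
                        min_reads = 7, af1_min = 0.5001) {
  validate_records(records)
  stages <- list(
    quality = function(x) filter_quality(x, q_min),
    coverage = function(x) filter_coverage(x, cov_max),
    support = function(x) filter_support(x, min_reads),
    homozygous = function(x) filter_homozygous(x, af1_min),
    private = function(x) filter_private(x, comparison_sets),
    uv_signature = filter_uv_signature
  )
  counts <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  cur <- records
  for (nm in names(stages)) {
    n_in <- nrow(cur)
    cur <- stages[[nm]](cur)
    counts <- rbind(counts, data.frame(stage = nm, n_in = n_in, n_out = nrow(cur)))
  }
  survivors <- cur
  if (!is.null(models) && !is.null(genome)) {
    ann <- annotate_consequence(survivors, models, genome)
    survivors <- cbind(survivors, ann)
    candidates <- survivors[survivors$consequence %in% AMINO_ACID_CHANGING, , drop = FALSE]
    counts <- rbind(counts, data.frame(stage = "consequence",
                                       n_in = nrow(survivors),
                                       n_out = nrow(candidates)))
  } else {
    candidates <- survivors
  }
  structure(list(counts = counts, survivors = survivors, candidates = candidates),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("candidates: %d\n", nrow(x$candidates)))
  invisible(x)
}
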