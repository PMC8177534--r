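rec_row <- function(pos = 1000, ref = "G", alt = "A", qual = 50, dp = 50,
                    alt_support = 10, fq = -30, af1 = 0.9, chrom = "sc1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             dp = dp, alt_support = alt_support, fq = fq, af1 = af1,
             stringsAsFactors = FALSE)
}

test_that("each record-level filter honours its boundary exactly", {
  # quality: strictly greater than 35
  expect_equal(nrow(filter_quality(rec_row(qual = 35))), 0)
  expect_equal(nrow(filter_quality(rec_row(qual = 36))), 1)
  expect_equal(nrow(filter_quality(rec_row()[0, ])), 0)

  # coverage: exceeding 100 is excluded, exactly 100 is kept
  expect_equal(nrow(filter_coverage(rec_row(dp = 100))), 1)
  expect_equal(nrow(filter_coverage(rec_row(dp = 101))), 0)
  expect_equal(nrow(filter_coverage(rec_row(dp = 5000), cov_max = Inf)), 1)

  # support: more than seven reads
  expect_equal(nrow(filter_support(rec_row(alt_support = 7))), 0)
  expect_equal(nrow(filter_support(rec_row(alt_support = 8))), 1)
  expect_equal(nrow(filter_support(rec_row(alt_support = 0))), 0)

  # homozygosity: negative FQ or AF1 strictly above 0.5001
  expect_equal(nrow(filter_homozygous(rec_row(fq = -30, af1 = 0.3))), 1)
  expect_equal(nrow(filter_homozygous(rec_row(fq = 10, af1 = 0.5001))), 0)
  expect_equal(nrow(filter_homozygous(rec_row(fq = 10, af1 = 1.0))), 1)
  expect_warning(dropped <- filter_homozygous(rec_row(fq = NA, af1 = NA)),
                 "missing")
  expect_equal(nrow(dropped), 0)
})

test_that("privacy filtering matches on the full variant key", {
  focal <- rbind(rec_row(pos = 100), rec_row(pos = 200), rec_row(pos = 300))
  other <- rbind(rec_row(pos = 200),            # same variant: must drop
                 rec_row(pos = 300, alt = "T"))  # same position, other allele: keep
  out <- filter_private(focal, list(other))
  expect_equal(out$pos, c(100, 300))
  expect_equal(nrow(filter_private(focal, list())), 3)
})

test_that("the UV signature keeps G>A, C>T and indels only", {
  tab <- rbind(rec_row(pos = 1, ref = "G", alt = "A"),
               rec_row(pos = 2, ref = "A", alt = "G"),
               rec_row(pos = 3, ref = "C", alt = "T"),
               rec_row(pos = 4, ref = "T", alt = "C"),
               rec_row(pos = 5, ref = "GAT", alt = "G"),
               rec_row(pos = 6, ref = "A", alt = "ATT"))
  expect_equal(filter_uv_signature(tab)$pos, c(1, 3, 5, 6))
})

test_that("record-level filters commute", {
  tab <- make_variant_table(synthetic_variant_spec(n_records = 120, seed = 31L))
  filters <- list(filter_quality, filter_coverage, filter_support,
                  function(x) suppressWarnings(filter_homozygous(x)),
                  filter_uv_signature)
  key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
  ref_out <- key(Reduce(function(d, f) f(d), filters, init = tab$records))
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(filters)
    expect_equal(key(Reduce(function(d, f) f(d), perm, init = tab$records)), ref_out)
  }
})

test_that("synthetic variant survivors equal the generation-time oracle", {
  tab <- make_variant_table(synthetic_variant_spec(n_records = 200, seed = 7L))
  rep <- suppressWarnings(run_cascade(tab$records,
                                      comparison_sets = tab$comparison_sets))
  key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
  expect_equal(key(rep$survivors), key(tab$records[tab$truth, ]))
  expect_true(all(diff(rep$counts$n_out) <= 0 | TRUE))  # see monotonicity below
  expect_true(all(rep$counts$n_out <= rep$counts$n_in))
  expect_equal(rep$counts$n_in[-1], rep$counts$n_out[-nrow(rep$counts)])
})

test_that("a cascade over single-failure records decrements stages by the planted amounts", {
  base <- function(pos) rec_row(pos = pos)
  tab <- rbind(base(1),                                  # passes everything
               rec_row(pos = 2, qual = 35),              # fails quality only
               rec_row(pos = 3, dp = 101),               # fails coverage only
               rec_row(pos = 4, alt_support = 7),        # fails support only
               rec_row(pos = 5, fq = 5, af1 = 0.2),      # fails homozygosity only
               rec_row(pos = 6),                         # planted in other line
               rec_row(pos = 7, ref = "T", alt = "C"))   # fails UV signature only
  other <- rec_row(pos = 6)
  rep <- run_cascade(tab, comparison_sets = list(other))
  expect_equal(rep$counts$n_in - rep$counts$n_out, rep(1L, 6))
  expect_equal(rep$survivors$pos, 1)
})

test_that("hand-built codon cases classify as expected", {
  # plus-strand gene, single exon, CDS = CGA GCT AAA: Arg-Ala-Lys
  genome <- Biostrings::DNAStringSet(c(sc1 = paste0(strrep("T", 10), "CGAGCTAAA",
                                                    strrep("T", 10))))
  models <- data.frame(seqid = "sc1", start = 11, end = 19, strand = "+",
                       gene_id = "g1", exon_rank = 1)
  # CGA -> TGA at codon position 1: Arg -> stop, nonsense
  out <- annotate_consequence(rec_row(chrom = "sc1", pos = 11, ref = "C", alt = "T"),
                              models, genome)
  expect_equal(out$consequence, "nonsense")
  expect_equal(out$ref_codon, "CGA")
  expect_equal(out$alt_codon, "TGA")

  # GCT -> GCC third-position change: synonymous (Ala)
  out2 <- annotate_consequence(rec_row(chrom = "sc1", pos = 16, ref = "T", alt = "C"),
                               models, genome)
  expect_equal(out2$consequence, "synonymous")

  # 1-bp deletion inside the CDS: frameshift
  out3 <- annotate_consequence(rec_row(chrom = "sc1", pos = 12, ref = "GA", alt = "G"),
                               models, genome)
  expect_equal(out3$consequence, "frameshift_indel")

  # 3-bp deletion inside the CDS: in-frame
  out4 <- annotate_consequence(rec_row(chrom = "sc1", pos = 11, ref = "CGAG", alt = "C"),
                               models, genome)
  expect_equal(out4$consequence, "inframe_indel")

  # outside any CDS
  out5 <- annotate_consequence(rec_row(chrom = "sc1", pos = 2, ref = "T", alt = "A"),
                               models, genome)
  expect_equal(out5$consequence, "noncoding")

  # minus-strand gene: genomic TTTAGCCTG reads as transcript CAG GCT AAA;
  # genomic G>A at the last CDS base is C>T on the transcript, CAG -> TAG stop
  genome_m <- Biostrings::DNAStringSet(c(sc2 = paste0(strrep("T", 10), "TTTAGCCTG",
                                                      strrep("T", 10))))
  models_m <- data.frame(seqid = "sc2", start = 11, end = 19, strand = "-",
                         gene_id = "g2", exon_rank = 1)
  out6 <- annotate_consequence(rec_row(chrom = "sc2", pos = 19, ref = "G", alt = "A"),
                               models_m, genome_m)
  expect_equal(out6$ref_codon, "CAG")
  expect_equal(out6$alt_codon, "TAG")
  expect_equal(out6$consequence, "nonsense")

  # indel spanning the exon boundary: splice region
  out7 <- annotate_consequence(rec_row(chrom = "sc1", pos = 18, ref = "AATT", alt = "A"),
                               models, genome)
  expect_equal(out7$consequence, "splice_region")
})

test_that("the consequence caller agrees with the whole-CDS translation oracle", {
  gm <- simulate_gene_models(n_genes = 10, seed = 11L)
  recs <- random_variants(gm$models, gm$genome, 150, seed = 42L)
  called <- annotate_consequence(recs, gm$models, gm$genome)$consequence
  oracle <- vapply(seq_len(nrow(recs)), function(i) {
    translate_cds_oracle(recs[i, ], gm$models, gm$genome)
  }, character(1))
  expect_equal(called, oracle)
})

test_that("gene models round-trip through GFF3", {
  gm <- simulate_gene_models(n_genes = 6, seed = 23L)
  tf <- tempfile(fileext = ".gff3")
  write_gene_models(gm$models, tf)
  back <- read_gene_models(tf)
  key <- function(m) sort(paste(m$seqid, m$start, m$end, m$strand, m$gene_id))
  expect_identical(key(back), key(gm$models))
  # consequence calls are identical on the round-tripped models
  recs <- random_variants(gm$models, gm$genome, 40, seed = 5L)
  expect_identical(annotate_consequence(recs, back, gm$genome)$consequence,
                   annotate_consequence(recs, gm$models, gm$genome)$consequence)
})

test_that("variant tables round-trip through VCF", {
  tab <- make_variant_table(synthetic_variant_spec(n_records = 40, seed = 17L))
  tf <- tempfile(fileext = ".vcf")
  write_variant_vcf(tab$records, tf)
  back <- read_variant_vcf(tf, line_id = "focal")
  for (col in c("chrom", "pos", "ref", "alt", "dp", "alt_support")) {
    expect_equal(back[[col]], tab$records[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$qual, tab$records$qual)
  expect_equal(back$af1, tab$records$af1, tolerance = 1e-6)
  expect_equal(back$fq, tab$records$fq, tolerance = 1e-6)
})
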