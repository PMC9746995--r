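# cohort merge, retention filters, consequence annotation, VCF round-trip

toy_sheet <- function(n = 4, pools = 2) {
  read_sample_sheet(data.frame(
    sample_id = paste0("S", seq_len(n)),
    fwd_barcode = example_sheet(n)$fwd_barcode,
    rev_barcode = example_sheet(n)$rev_barcode,
    pool_id = paste0("pool", rep(seq_len(pools), length.out = n))))
}

call_row <- function(sample, pos, gt, locus = "toyA", depth = 100L,
                     ref = "A", alt = "G", chrom = "1", ratio = 0.55) {
  data.table::data.table(
    sample_id = sample, locus_id = locus, chrom = chrom, pos = as.integer(pos),
    insert_offset = 0L, ref = ref, alt = alt, genotype = gt,
    depth = as.integer(depth), ad_ref = 50L, ad_alt = 50L,
    allele_ratio = ratio)
}

test_that("overlapping-amplicon duplicates merge to one call per sample", {
  panel <- mini_panel(random_dna(60))
  sheet <- toy_sheet(2)
  calls <- rbind(
    call_row("S1", 1500, "het", locus = "ampA", depth = 120),
    call_row("S1", 1500, "het", locus = "ampB", depth = 80),
    call_row("S2", 1500, "hom_ref", locus = "ampA", depth = 90, alt = NA))
  tab <- merge_cohort(calls, sheet, panel)
  expect_identical(nrow(tab$sites), 1L)
  expect_identical(tab$sites$locus_ids, "ampA,ampB")
  m <- tab$calls[which(tab$calls$sample_id == "S1"), ]
  expect_identical(nrow(m), 1L)
  expect_identical(m$depth, 120L)      # deeper amplicon wins
  expect_false(m$conflict)
  # disagreeing duplicates keep the deeper call and flag the conflict
  calls2 <- rbind(
    call_row("S1", 1500, "het", locus = "ampA", depth = 120),
    call_row("S1", 1500, "hom_alt", locus = "ampB", depth = 80))
  tab2 <- merge_cohort(calls2, sheet, panel)
  m2 <- tab2$calls[which(tab2$calls$sample_id == "S1"), ]
  expect_identical(m2$genotype, "het")
  expect_true(m2$conflict)
})

test_that("unique site count is invariant to duplicating an amplicon", {
  panel <- mini_panel(random_dna(60))
  sheet <- toy_sheet(3)
  base <- rbind(call_row("S1", 1500, "het"), call_row("S2", 1500, "hom_alt"),
                call_row("S1", 1600, "het", alt = "T"))
  dup <- rbind(base, data.table::copy(base)[, locus_id := "toyA_copy"])
  t1 <- merge_cohort(base, sheet, panel)
  t2 <- merge_cohort(dup, sheet, panel)
  expect_identical(nrow(t1$sites), nrow(t2$sites))
  # record count >= unique sites, equality iff no overlap
  expect_gte(nrow(dup), nrow(t2$sites))
  expect_identical(nrow(base[!is.na(base$alt), ]),
                   nrow(t1$sites) + 1L)  # S1+S2 share one site
})

test_that("retention filters drop singletons and single-pool sites", {
  panel <- mini_panel(random_dna(60))
  sheet <- toy_sheet(4, pools = 2)  # S1,S3 pool1; S2,S4 pool2
  calls <- rbind(
    call_row("S1", 1500, "het"),                      # singleton
    call_row("S1", 1600, "het", alt = "T"),           # 3 carriers, 1 pool
    call_row("S3", 1600, "het", alt = "T"),
    call_row("S1", 1700, "hom_alt", alt = "C"),       # 2 carriers, 2 pools
    call_row("S2", 1700, "het", alt = "C"))
  sheet2 <- read_sample_sheet(data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    fwd_barcode = example_sheet(4)$fwd_barcode,
    rev_barcode = example_sheet(4)$rev_barcode,
    pool_id = c("pool1", "pool2", "pool1", "pool2")))
  tab <- apply_cohort_filters(merge_cohort(calls, sheet2, panel),
                              filter_config())
  s <- tab$sites
  expect_identical(s$retained[s$pos == 1500], FALSE)
  expect_identical(s$reason[s$pos == 1500], "singleton")
  expect_identical(s$retained[s$pos == 1600], FALSE)
  expect_identical(s$reason[s$pos == 1600], "single_pool")
  expect_identical(s$retained[s$pos == 1700], TRUE)
  # filtering is idempotent
  tab2 <- apply_cohort_filters(tab, filter_config())
  expect_equal(as.data.frame(tab2$sites), as.data.frame(tab$sites))
  rep <- retention_report(tab)
  expect_identical(nrow(rep), 3L)
})

test_that("exonic consequences are translated strand- and frame-aware", {
  # plus strand: GCA (A) -> TCA (S) at absolute codon 296
  ins <- random_dna(120)
  substr(ins, 51, 53) <- "GCA"
  cds <- data.table::data.table(locus_id = "toyA", cds_start = 1021L,
                                cds_end = 1100L, strand = "+", frame = 0L,
                                cds_offset = 855L)
  # codon 296 starts at cds position 885 = offset 1021 + 30 -> pos 1051
  panel <- mini_panel(ins, cds = cds)
  an <- annotate_consequence("1", 1051L, "G", "T", panel)
  expect_identical(an$effect, "missense")
  expect_identical(an$codon_ref, "GCA")
  expect_identical(an$codon_alt, "TCA")
  expect_identical(an$aa_change, "A296S")
  # synonymous: CTG -> CTA (both Leu), third codon position
  ins2 <- random_dna(120)
  substr(ins2, 51, 53) <- "CTG"
  panel2 <- mini_panel(ins2, cds = cds)
  an2 <- annotate_consequence("1", 1053L, "G", "A", panel2)
  expect_identical(an2$effect, "synonymous")
  expect_identical(an2$aa_ref, "L")
  # stop gained: TAC -> TAA
  ins3 <- random_dna(120)
  substr(ins3, 51, 53) <- "TAC"
  panel3 <- mini_panel(ins3, cds = cds)
  an3 <- annotate_consequence("1", 1053L, "C", "A", panel3)
  expect_identical(an3$effect, "stop_gained")
})

test_that("minus-strand codons are built from the reverse complement", {
  ins <- random_dna(60)
  substr(ins, 20, 22) <- "CAT"  # transcript reads ATG (M) right-to-left
  cds <- data.table::data.table(locus_id = "toyA", cds_start = 1011L,
                                cds_end = 1022L, strand = "-", frame = 0L,
                                cds_offset = 0L)
  panel <- mini_panel(ins, cds = cds)
  # transcript codon 1 first base = genomic pos 1022 (insert offset 21, "T")
  an <- annotate_consequence("1", 1022L, "T", "C", panel)
  expect_identical(an$codon_ref, "ATG")
  expect_identical(an$aa_ref, "M")
  expect_identical(an$codon_alt, "GTG")
  expect_identical(an$aa_alt, "V")
  expect_identical(an$aa_pos, 1L)
  expect_identical(an$effect, "missense")
})

test_that("the 3/8 splice window separates splice_region from intronic", {
  ins <- random_dna(100)
  cds <- data.table::data.table(locus_id = "toyA", cds_start = 1031L,
                                cds_end = 1070L, strand = "+", frame = 0L,
                                cds_offset = 0L)
  panel <- mini_panel(ins, cds = cds)
  # intronic, 5 bases upstream of the exon start -> splice_region
  an5 <- annotate_consequence("1", 1026L, "A", "G", panel)
  expect_identical(an5$effect, "splice_region")
  expect_identical(an5$dist_exon_boundary, 5L)
  # intronic, 8 bases -> still splice_region (boundary of the window)
  expect_identical(annotate_consequence("1", 1023L, "A", "G", panel)$effect,
                   "splice_region")
  # intronic, 9 bases -> plain intronic
  an9 <- annotate_consequence("1", 1022L, "A", "G", panel)
  expect_identical(an9$effect, "intronic")
  # exonic within 3 bases of the boundary keeps its coding effect but
  # sets the near_splice flag
  anx <- annotate_consequence("1", 1032L, substr(ins, 32, 32), "A", panel)
  expect_true(anx$near_splice)
  expect_true(anx$effect %in% c("synonymous", "missense", "stop_gained"))
})

test_that("codons cut by the segment edge are flagged, not guessed", {
  ins <- random_dna(100)
  cds <- data.table::data.table(locus_id = "toyA", cds_start = 1031L,
                                cds_end = 1041L, strand = "+", frame = 0L,
                                cds_offset = 0L)
  panel <- mini_panel(ins, cds = cds)
  # cds length 11: the fourth codon (cds pos 9-11) runs off the segment
  an <- annotate_consequence("1", 1040L, substr(ins, 40, 40), "A", panel)
  expect_identical(an$effect, "truncated_codon")
  expect_error(annotate_consequence("1", 99999L, "A", "G", panel),
               "no amplicon")
})

test_that("cohort VCF writes, round-trips byte-stably and recounts", {
  panel <- mini_panel(random_dna(60))
  sheet2 <- read_sample_sheet(data.frame(
    sample_id = c("S1", "S2"),
    fwd_barcode = example_sheet(2)$fwd_barcode,
    rev_barcode = example_sheet(2)$rev_barcode,
    pool_id = c("pool1", "pool2")))
  calls <- rbind(call_row("S1", 1500, "het"),
                 call_row("S2", 1500, "hom_alt", ratio = 0.98))
  tab <- apply_cohort_filters(merge_cohort(calls, sheet2, panel),
                              filter_config())
  vcf1 <- tempfile(fileext = ".vcf")
  write_cohort_vcf(tab, vcf1)
  lines <- readLines(vcf1)
  expect_identical(sum(!startsWith(lines, "#")), 1L)   # one data line
  parsed <- read_cohort_vcf(vcf1)
  expect_identical(parsed$samples, c("S1", "S2"))
  expect_identical(parsed$calls$genotype, c("het", "hom_alt"))

  # write -> parse -> rebuild -> write is byte-stable
  tab_rt <- merge_cohort(
    data.table::data.table(
      sample_id = parsed$calls$sample_id, locus_id = "toyA",
      chrom = parsed$calls$chrom, pos = parsed$calls$pos, insert_offset = 0L,
      ref = parsed$calls$ref, alt = parsed$calls$alt,
      genotype = parsed$calls$genotype, depth = parsed$calls$depth,
      ad_ref = parsed$calls$ad_ref, ad_alt = parsed$calls$ad_alt,
      allele_ratio = parsed$calls$allele_ratio),
    sheet2, panel)
  tab_rt$sites$locus_ids <- tab$sites$locus_ids
  vcf2 <- tempfile(fileext = ".vcf")
  write_cohort_vcf(apply_cohort_filters(tab_rt, filter_config()), vcf2)
  expect_identical(readLines(vcf2), readLines(vcf1))

  # a standard VCF parser accepts the file
  skip_if_not_installed("VariantAnnotation")
  v <- suppressWarnings(VariantAnnotation::readVcf(vcf1))
  expect_identical(dim(v), c(1L, 2L))
  gt <- VariantAnnotation::geno(v)$GT
  expect_identical(unname(gt[1, ]), c("0/1", "1/1"))
})

test_that("alt allele frequency recomputed from the VCF matches the table", {
  st <- make_study(n_samples = 6, coverage = 60, error = 0, mistag = 0,
                   seed = 301)
  pools <- lapply(st$sims, function(s) list(r1 = s$r1, r2 = s$r2))
  res <- run_pipeline(st$panel, st$sheet, pools,
                      vcf_path = tempfile(fileext = ".vcf"))
  stats <- res$site_stats
  parsed <- read_cohort_vcf(res$vcf_path)
  for (i in seq_len(nrow(parsed$sites))) {
    s <- parsed$sites[i]
    g <- parsed$calls[parsed$calls$pos == s$pos & parsed$calls$chrom == s$chrom, ]
    g <- g[g$genotype != "missing", ]
    freq <- 100 * sum(c(het = 1, hom_alt = 2, hom_ref = 0)[g$genotype]) /
      (2 * nrow(g))
    expect_equal(freq,
                 stats$alt_freq_pct[stats$pos == s$pos & stats$chrom == s$chrom])
  }
  expect_gte(nrow(parsed$sites), 1L)
})
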