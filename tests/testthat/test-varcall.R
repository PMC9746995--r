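# glocal alignment, pileup construction, allele-ratio genotyping

test_that("exact and near-exact reads align at the right offset", {
  panel <- example_panel()
  ins <- panel$inserts[["Rdl_Aeg"]]
  read <- substr(ins, 31, 280)
  a <- align_to_insert(read, ins)
  expect_identical(a$insert_start, 30L)
  expect_identical(a$cigar, "250M")
  expect_identical(a$score, 250L)
  # one substitution: same placement, score drops by 2
  read2 <- read
  substr(read2, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read2, 100, 100))[1]
  a2 <- align_to_insert(read2, ins)
  expect_identical(a2$insert_start, 30L)
  expect_identical(a2$cigar, "250M")
  expect_identical(a2$score, 248L)
  expect_error(align_to_insert("", ins), "empty read")
})

test_that("alignment scores equal a full DP oracle on random pairs", {
  set.seed(31)
  for (rep in seq_len(200L)) {
    n <- sample(20:60, 1)
    m <- sample(5:n, 1)
    ref <- random_dna(n)
    # half the cases are mutated substrings, half unrelated sequence
    if (rep %% 2 == 0) {
      start <- sample(seq_len(n - m + 1L), 1)
      read <- substr(ref, start, start + m - 1L)
      nmut <- sample(0:3, 1)
      for (x in seq_len(nmut)) {
        p <- sample(m, 1)
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (m > 10 && rep %% 4 == 0) read <- paste0(substr(read, 1, 4),
                                                  substr(read, 7, m))
    } else {
      read <- random_dna(m)
    }
    got <- align_to_insert(read, ref)$score
    want <- oracle_glocal_score(read, ref)
    expect_identical(as.integer(got), as.integer(want),
                     info = paste(read, ref))
  }
})

test_that("indels are aligned, left-aligned and keyed VCF-style", {
  # reference with a homopolymer so left-alignment is exercised
  ins <- paste0("ACGTACGTAC", "TTTTT", "GACGATTACA", "GGCCGGCCAA")
  read_del <- paste0("ACGTACGTAC", "TTTT", "GACGATTACA")  # one T deleted
  a <- align_to_insert(read_del, ins)
  expect_identical(a$insert_start, 0L)
  pl <- build_pileup(data.table::data.table(
    pair_id = "p1", mate = 1L, insert_start = a$insert_start,
    cigar = a$cigar, seq = read_del, qual = strrep("F", nchar(read_del))),
    ins, filter_config(min_depth = 1, min_allele_depth = 1))
  indel <- pl$ad[grepl(">", pl$ad$allele), ]
  expect_identical(nrow(indel), 1L)
  # left-aligned anchor: base before the first T (offset 9)
  expect_identical(indel$insert_offset, 9L)
  expect_identical(indel$allele, "CT>C")

  read_ins <- paste0("ACGTACGTAC", "TTTTTT", "GACGATTACA")  # one T inserted
  b <- align_to_insert(read_ins, ins)
  pl2 <- build_pileup(data.table::data.table(
    pair_id = "p1", mate = 1L, insert_start = b$insert_start,
    cigar = b$cigar, seq = read_ins, qual = strrep("F", nchar(read_ins))),
    ins, filter_config())
  indel2 <- pl2$ad[grepl(">", pl2$ad$allele), ]
  expect_identical(indel2$insert_offset, 9L)
  expect_identical(indel2$allele, "C>CT")
})

test_that("pileup applies the Q30 base-quality filter per called base", {
  # 60 A bases at Q37, 10 G bases at Q20 at one offset
  aln <- site_alignments(c(rep("A", 60), rep("G", 10)),
                         quals = c(rep(37L, 60), rep(20L, 10)))
  pl <- build_pileup(aln, "A", filter_config())
  col <- pileup_column(pl, 0L)
  expect_identical(col$allele_depths, c(A = 60L))
  expect_identical(col$raw_depth, 70L)
  # no reads -> empty pileup
  empty <- build_pileup(NULL, "A", filter_config())
  expect_identical(nrow(empty$ad), 0L)
  expect_identical(pileup_column(empty, 0L)$raw_depth, 0L)
})

test_that("allele depths equal a brute-force recount of alignment records", {
  st <- make_study(n_samples = 2, coverage = 30, error = 0.02, mistag = 0,
                   seed = 61)
  sim <- st$sims[[1]]
  sub <- st$sheet[st$sheet$pool_id == names(st$sims)[1], ]
  dm <- demultiplex(sim$r1, sim$r2, st$panel, sub)
  g <- dm$groups[which(dm$groups$sample_id == sub$sample_id[1] &
                         dm$groups$locus_id == "Ace1"), ]
  ins <- st$panel$inserts[["Ace1"]]
  aln <- ampliseqr:::align_group(g, ins)
  cfg <- filter_config()
  pl <- build_pileup(aln, ins, cfg)
  # oracle: expand every M run by hand, dedup mates by max quality
  recs <- list()
  for (i in seq_len(nrow(aln))) {
    stopifnot(grepl("^[0-9]+M$", aln$cigar[i]))
    L <- nchar(aln$seq[i])
    recs[[i]] <- data.frame(
      pair = aln$pair_id[i],
      off = aln$insert_start[i] + seq_len(L) - 1L,
      base = strsplit(aln$seq[i], "")[[1]],
      q = as.integer(charToRaw(aln$qual[i])) - 33L)
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$pair, recs$off, -recs$q), ]
  recs <- recs[!duplicated(recs[, c("pair", "off")]), ]
  keep <- recs[recs$q >= cfg$min_base_quality, ]
  want <- aggregate(q ~ off + base, keep, length)
  for (r in seq_len(nrow(want))) {
    got <- pl$ad$count[pl$ad$insert_offset == want$off[r] &
                         pl$ad$allele == want$base[r]]
    expect_identical(got, as.integer(want$q[r]))
  }
  expect_identical(sum(pl$ad$count), nrow(keep))
})

test_that("overlapping mate bases are counted once, keeping higher quality", {
  ins <- random_dna(40)
  aln <- data.table::data.table(
    pair_id = c("p1", "p1"), mate = c(1L, 2L), insert_start = c(0L, 10L),
    cigar = c("30M", "30M"),
    seq = c(substr(ins, 1, 30), substr(ins, 11, 40)),
    qual = c(strrep("F", 30), strrep("5", 30)))  # Q37 vs Q20
  pl <- build_pileup(aln, ins, filter_config())
  # overlap offsets 10..29 must have raw depth 1, not 2
  raw <- pl$raw$raw_depth[pl$raw$insert_offset %in% 10:29]
  expect_true(all(raw == 1L))
  # and the Q37 base wins, so the allele passes the Q30 filter
  ad <- pl$ad[pl$ad$insert_offset %in% 10:29, ]
  expect_identical(nrow(ad), 20L)
  # mate-2-only offsets (30..39) are Q20: raw only
  expect_identical(sum(pl$ad$insert_offset >= 30L), 0L)
  expect_true(all(pl$raw$raw_depth[pl$raw$insert_offset %in% 30:39] == 1L))
})

test_that("genotype_site applies depth, allele-depth and ratio thresholds", {
  cfg <- filter_config()
  gt <- function(depths, ref = "A") {
    genotype_site(list(allele_depths = depths, raw_depth = sum(depths),
                       ref = ref), cfg)
  }
  # ratio 0.9 >= 0.8 -> homozygous reassignment of the major allele
  g1 <- gt(c(A = 90L, T = 10L))
  expect_identical(g1$genotype, "hom_ref")
  expect_equal(g1$allele_ratio, 0.9)
  # ratio 0.6 < 0.8 -> heterozygous
  g2 <- gt(c(A = 60L, T = 40L))
  expect_identical(g2$genotype, "het")
  expect_equal(g2$allele_ratio, 0.6)
  # minor allele below 10-fold allele depth: ignored, ratio 1.0
  g3 <- gt(c(A = 45L, T = 5L))
  expect_identical(g3$genotype, "hom_ref")
  expect_equal(g3$allele_ratio, 1.0)
  # filtered depth below 50 -> missing
  g4 <- gt(c(A = 30L, T = 10L))
  expect_identical(g4$genotype, "missing")
  expect_true(is.na(g4$allele_ratio))
  # hom_alt at ratio boundary exactly 0.8 (inclusive)
  g5 <- gt(c(T = 80L, A = 20L))
  expect_identical(g5$genotype, "hom_alt")
  expect_equal(g5$allele_ratio, 0.8)
})

test_that("genotyping is monotone in min_depth and hom_ratio_threshold", {
  set.seed(17)
  for (rep in seq_len(50L)) {
    nref <- sample(0:120, 1); nalt <- sample(0:120, 1)
    col <- list(allele_depths = c(A = nref, T = nalt)[c(nref, nalt) > 0],
                raw_depth = nref + nalt, ref = "A")
    if (length(col$allele_depths) == 0L) next
    g_lo <- genotype_site(col, filter_config(min_depth = 30))
    g_hi <- genotype_site(col, filter_config(min_depth = 80))
    # raising min_depth never converts missing -> called
    if (g_lo$genotype == "missing") expect_identical(g_hi$genotype, "missing")
    r_lo <- genotype_site(col, filter_config(hom_ratio_threshold = 0.75))
    r_hi <- genotype_site(col, filter_config(hom_ratio_threshold = 0.95))
    # raising the ratio threshold never converts het -> hom
    if (r_lo$genotype == "het") {
      expect_true(r_hi$genotype %in% c("het", "missing"))
    }
  }
})

test_that("truth genotypes are recovered at coverage 200, error 0.1%", {
  set.seed(23)
  cfg <- filter_config()
  n_sites <- 1000L
  truth <- sample(c("hom_ref", "het", "hom_alt"), n_sites, replace = TRUE)
  correct <- 0L
  discord_het_hom <- TRUE
  for (i in seq_len(n_sites)) {
    p_alt <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[[truth[i]]]
    base <- ifelse(stats::runif(200) < p_alt, "T", "A")
    err <- stats::runif(200) < 0.001
    base[err] <- vapply(base[err],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
    pl <- build_pileup(site_alignments(base), "A", cfg)
    g <- genotype_site(pileup_column(pl, 0L), cfg)
    if (g$genotype == truth[i]) {
      correct <- correct + 1L
    } else if (!(g$genotype == "het" || truth[i] == "het")) {
      discord_het_hom <- FALSE
    }
  }
  expect_gte(correct / n_sites, 0.99)
  # any discordance is het<->hom, never ref<->alt flips
  expect_true(discord_het_hom)
})

test_that("heterozygote allele ratio converges to 0.5 at high coverage", {
  set.seed(29)
  cfg <- filter_config()
  for (rep in 1:3) {
    base <- ifelse(stats::runif(10000) < 0.5, "T", "A")
    pl <- build_pileup(site_alignments(base), "A", cfg)
    g <- genotype_site(pileup_column(pl, 0L), cfg)
    expect_identical(g$genotype, "het")
    expect_lt(abs(g$allele_ratio - 0.5), 0.02)
  }
})

test_that("call_sample_variants reports planted variants and known sites", {
  panel <- example_panel()
  sheet <- example_sheet(1)
  spec <- genotype_spec(data.frame(sample_id = "M001", locus_id = "Rdl_Aeg",
                                   insert_offset = 235L, ref = "G",
                                   alt = "T", genotype = "hom_alt"),
                        panel, sheet)
  sim <- simulate_pool(panel, sheet, spec,
                       sim_config(coverage = 200, base_error_rate = 0.001,
                                  seed = 37), tempfile("cv"))
  dm <- demultiplex(sim$r1, sim$r2, panel, sheet)
  calls <- call_sample_variants(dm$groups, panel)
  # exactly one variant site, hom_alt
  vars <- calls[which(!is.na(calls$alt)), ]
  expect_identical(nrow(vars), 1L)
  expect_identical(vars$pos, 41847790L)
  expect_identical(vars$genotype, "hom_alt")
  expect_identical(vars$alt, "T")
  # all four known resistance sites are reported even when wild-type
  known <- merge(calls, panel$known_sites,
                 by.x = c("locus_id", "pos"), by.y = c("locus_id", "pos"))
  expect_identical(nrow(known), 4L)
  wild <- known[which(known$pos != 41847790L), ]
  expect_true(all(wild$genotype == "hom_ref"))
})

test_that("a wild-type sample yields no variant sites", {
  panel <- example_panel()
  sheet <- example_sheet(1)
  spec <- genotype_spec(data.frame(sample_id = character(),
                                   locus_id = character(),
                                   insert_offset = integer(),
                                   ref = character(), alt = character(),
                                   genotype = character()), panel, sheet)
  sim <- simulate_pool(panel, sheet, spec,
                       sim_config(coverage = 80, seed = 41), tempfile("wt"))
  dm <- demultiplex(sim$r1, sim$r2, panel, sheet)
  calls <- call_sample_variants(dm$groups, panel)
  expect_identical(sum(!is.na(calls$alt)), 0L)
  expect_identical(nrow(calls), 4L)  # the known sites
  expect_true(all(calls$genotype == "hom_ref"))
})
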