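# End-to-end convenience driver: pooled FASTQ -> demultiplex -> align ->
# pileup -> joint genotyping -> cohort filters -> annotation -> VCF.

#' Run the full amplicon analysis pipeline
#'
#' Demultiplexes each pool with its slice of the sample sheet, aligns
#' and piles up every (mosquito, amplicon) read group, discovers
#' variant sites per amplicon, genotypes every sample at the union of
#' discovered and known resistance sites (so wild-type and missing
#' calls are explicit), merges into a cohort table, applies the
#' more-than-one-mosquito / two-pool retention filters, and annotates
#' retained sites.
#'
#' @param panel an `amp_panel`.
#' @param sheet a `sample_sheet` spanning all pools.
#' @param pools named list (names = pool ids) of `list(r1 = , r2 = )`
#'   FASTQ paths.
#' @param cfg a `filter_config`.
#' @param vcf_path optional path; when given the retained cohort VCF is
#'   written there.
#' @return list with `cohort` (filtered `cohort_table`), `annotations`,
#'   `site_stats`, `demux_stats` (per pool) and `vcf_path`.
#' @export
run_pipeline <- function(panel, sheet, pools, cfg = filter_config(),
                         vcf_path = NULL) {
  bad <- setdiff(names(pools), unique(sheet$pool_id))
  if (length(bad)) stop("pool not in sheet: ", paste(bad, collapse = ", "))
  groups <- list(); dstats <- list()
  for (pid in names(pools)) {
    sub <- sheet[sheet$pool_id == pid, ]
    dm <- demultiplex(pools[[pid]]$r1, pools[[pid]]$r2, panel, sub, cfg)
    groups[[pid]] <- dm$groups
    dstats[[pid]] <- dm$stats
  }
  groups <- data.table::rbindlist(groups)
  pls <- sample_pileups(groups, panel, cfg)

  # union of variant offsets per locus across samples, plus known sites
  union_offs <- list()
  for (sid in names(pls)) {
    for (lid in names(pls[[sid]])) {
      union_offs[[lid]] <- union(union_offs[[lid]],
                                 variant_offsets(pls[[sid]][[lid]], cfg))
    }
  }
  for (lid in unique(panel$known_sites$locus_id)) {
    ks <- panel$known_sites[panel$known_sites$locus_id == lid, ]
    union_offs[[lid]] <- union(union_offs[[lid]],
                               genomic_to_offset(panel, lid, ks$pos))
  }

  calls <- list()
  for (sid in sheet$sample_id) {
    for (lid in names(union_offs)) {
      offs <- sort(union_offs[[lid]])
      if (length(offs) == 0L) next
      pl <- pls[[sid]][[lid]]
      if (is.null(pl)) pl <- build_pileup(NULL, panel$inserts[[lid]], cfg)
      calls[[length(calls) + 1L]] <-
        genotype_offsets(pl, offs, panel, lid, sid, cfg)
    }
  }
  calls <- data.table::rbindlist(calls)
  tab <- merge_cohort(calls, sheet, panel)
  tab <- apply_cohort_filters(tab, cfg)
  ann <- annotate_cohort(tab)
  if (!is.null(vcf_path)) write_cohort_vcf(tab, vcf_path, ann)
  list(cohort = tab, annotations = ann,
       site_stats = cohort_site_stats(tab),
       demux_stats = dstats, vcf_path = vcf_path)
}
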