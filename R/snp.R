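#' Partition a hairpin into functional regions
#'
#' Splits the hairpin span (plus flanks) into disjoint regions: the seed of
#' each annotated mature (mature positions 2-8), the rest of each mature,
#' the pre-miRNA excluding the matures, and the upstream/downstream flanks
#' of width `flank_width`. Flank coordinates extend the hairpin coordinate
#' system: positions <= 0 are upstream, positions > hairpin length are
#' downstream.
#'
#' @param hairpin A [HairpinRecord-class] with at least one mature.
#' @param flank_width Flank width in nucleotides (default 200; 0 disables
#'   the flank regions).
#' @return A `data.frame` with columns `region`, `start`, `end`, `length`;
#'   regions with zero length are omitted.
#' @export
partitionRegions <- function(hairpin, flank_width = 200L) {
  m <- hairpinMatures(hairpin)
  if (!nrow(m)) stop("no matures annotated")
  flank_width <- as.integer(flank_width)
  n <- nchar(hairpinSeq(hairpin))
  rows <- list()
  addRow <- function(region, start, end) {
    start <- as.integer(start); end <- as.integer(end)
    if (end >= start)
      rows[[length(rows) + 1L]] <<- data.frame(
        region = region, start = start, end = end,
        length = end - start + 1L, stringsAsFactors = FALSE)
  }
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(m))) {
    s <- m$start[i]; e <- m$end[i]
    seedEnd <- min(s + 7L, e)
    addRow("seed", s + 1L, seedEnd)
    addRow("mature_excl_seed", s, s)              # position 1 of the mature
    if (seedEnd < e) addRow("mature_excl_seed", seedEnd + 1L, e)
    covered[s:e] <- TRUE
  }
  # pre-miRNA excluding matures: maximal uncovered runs
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values))
    if (!r$values[k]) addRow("premirna_excl_mature", starts[k], ends[k])
  if (flank_width > 0L) {
    addRow("flank_upstream", 1L - flank_width, 0L)
    addRow("flank_downstream", n + 1L, n + flank_width)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# region label of one position given a partition table, NA when uncovered
regionOfPosition <- function(partition, position) {
  hit <- partition$start <= position & partition$end >= position
  if (!any(hit)) NA_character_ else partition$region[which(hit)[1L]]
}

#' Pooled SNP density per functional region
#'
#' Pools SNP counts and region lengths over a dataset and reports the
#' density `N_snp * 1000 / L` (SNPs per kilobase) per region class. In
#' addition to the five primary regions the two flanks are also reported
#' pooled (`flank_pooled`). SNPs falling outside every region (beyond the
#' flank width, or on hairpins absent from the partition list) are dropped
#' with a warning.
#'
#' @param snps SNP table (see [loadSnpTable()]): columns `hairpin_id`,
#'   `position`, `flag`.
#' @param partitions Named list of partition tables, one per hairpin
#'   (see [regionPartitions()]).
#' @param flag_filter `"all"` or `"common_only"`.
#' @return A `data.frame` with columns `region`, `n_snp`, `length`,
#'   `density` (per kb; `NA` with a warning for zero-length regions).
#' @export
snpDensity <- function(snps, partitions, flag_filter = c("all", "common_only")) {
  flag_filter <- match.arg(flag_filter)
  if (flag_filter == "common_only")
    snps <- snps[snps$flag == "common", , drop = FALSE]
  regions <- c("seed", "mature_excl_seed", "premirna_excl_mature",
               "flank_upstream", "flank_downstream")
  lens <- stats::setNames(numeric(length(regions)), regions)
  for (p in partitions) {
    agg <- tapply(p$length, p$region, sum)
    lens[names(agg)] <- lens[names(agg)] + agg
  }
  nsnp <- stats::setNames(numeric(length(regions)), regions)
  dropped <- 0L
  for (i in seq_len(nrow(snps))) {
    p <- partitions[[snps$hairpin_id[i]]]
    reg <- if (is.null(p)) NA_character_ else
      regionOfPosition(p, snps$position[i])
    if (is.na(reg)) dropped <- dropped + 1L else nsnp[reg] <- nsnp[reg] + 1
  }
  if (dropped) warning(dropped, " SNP(s) outside every region dropped")
  out <- data.frame(region = c(regions, "flank_pooled"),
                    n_snp = c(nsnp, sum(nsnp[c("flank_upstream",
                                               "flank_downstream")])),
                    length = c(lens, sum(lens[c("flank_upstream",
                                                "flank_downstream")])),
                    stringsAsFactors = FALSE)
  zero <- out$length == 0
  if (any(zero & out$n_snp == 0))
    warning("zero-length region(s) skipped: ",
            paste(out$region[zero], collapse = ", "))
  out$density <- ifelse(zero, NA_real_, out$n_snp * 1000 / out$length)
  out
}

#' Partition every hairpin of a set
#'
#' @param set A [HairpinSet-class] (or list of records).
#' @inheritParams partitionRegions
#' @return Named list of partition tables; hairpins without matures are
#'   omitted with a warning.
#' @export
regionPartitions <- function(set, flank_width = 200L) {
  recs <- recordList(set)
  out <- list()
  skipped <- 0L
  for (r in recs) {
    p <- tryCatch(partitionRegions(r, flank_width), error = function(e) NULL)
    if (is.null(p)) skipped <- skipped + 1L else out[[hairpinId(r)]] <- p
  }
  if (skipped) warning(skipped, " hairpin(s) without matures skipped")
  out
}

#' Mean SNPs per pre-miRNA by disease association and mirtron status
#'
#' Counts SNPs within each hairpin's pre-miRNA span (flank SNPs excluded)
#' and averages per group of the 2x2 layout disease/non-disease x
#' mirtron/non-mirtron. Hairpins without SNPs contribute zeros. Empty
#' groups are reported with `NA` means.
#'
#' @param snps SNP table (columns `hairpin_id`, `position`, `flag`).
#' @param set A [HairpinSet-class]; mirtron status is read from the
#'   `"mirtron"` tag unless `mirtron_ids` is supplied.
#' @param disease_ids Character vector of disease-associated hairpin ids.
#' @param mirtron_ids Optional explicit mirtron id vector.
#' @param flag_filter `"all"` or `"common_only"`.
#' @return A `data.frame` with columns `disease`, `mirtron`, `n_hairpins`,
#'   `mean_snps`.
#' @export
snpOccurrenceByDisease <- function(snps, set, disease_ids,
                                   mirtron_ids = NULL,
                                   flag_filter = c("all", "common_only")) {
  flag_filter <- match.arg(flag_filter)
  if (flag_filter == "common_only")
    snps <- snps[snps$flag == "common", , drop = FALSE]
  recs <- recordList(set)
  ids <- vapply(recs, hairpinId, character(1L))
  lens <- vapply(recs, function(r) nchar(hairpinSeq(r)), integer(1L))
  inSpan <- snps$position >= 1L &
    snps$position <= lens[match(snps$hairpin_id, ids)]
  snps <- snps[!is.na(inSpan) & inSpan, , drop = FALSE]
  counts <- table(factor(snps$hairpin_id, levels = ids))
  isMir <- if (is.null(mirtron_ids))
    vapply(recs, function(r) "mirtron" %in% hairpinTags(r), logical(1L))
  else ids %in% mirtron_ids
  isDis <- ids %in% disease_ids
  grid <- expand.grid(disease = c(TRUE, FALSE), mirtron = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sel <- isDis == grid$disease[k] & isMir == grid$mirtron[k]
    data.frame(disease = grid$disease[k], mirtron = grid$mirtron[k],
               n_hairpins = sum(sel),
               mean_snps = if (any(sel)) mean(counts[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}
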