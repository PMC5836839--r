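#' Validated pipeline configuration
#'
#' Collects the paths and knobs every pipeline stage needs. The
#' configuration is validated up front and echoed into every report
#' header together with the coordinate/sign conventions, so that tables
#' derived from the reports are self-describing.
#'
#' @param hairpin_fasta,structures,matures Input paths (see
#'   [loadHairpins()]).
#' @param snps,branchpoints,rates Paths to the auxiliary tables (optional
#'   per subcommand).
#' @param mirtron_ids,robust_ids,disease_ids Paths to id-list files
#'   (optional).
#' @param outdir Output directory for reports.
#' @param flank_width Flank width, nucleotides (>= 0).
#' @param overhang_variant Overhang definition (see [computeOverhangs()]).
#' @param suspect_threshold Absolute overhang length flagged as suspect.
#' @param snp_flag_filter `"all"` or `"common_only"`.
#' @param robust_only Restrict every dataset to ids in `robust_ids`.
#' @param seed RNG seed used by stages with randomness.
#' @param simulate A [cohortSpec()] used by the `simulate` subcommand.
#' @return A validated list of class `RunConfig`.
#' @export
pipelineConfig <- function(hairpin_fasta = NULL, structures = NULL,
                           matures = NULL, snps = NULL, branchpoints = NULL,
                           rates = NULL, mirtron_ids = NULL,
                           robust_ids = NULL, disease_ids = NULL,
                           outdir = tempfile("mirfootprint-"),
                           flank_width = 200L,
                           overhang_variant = c("beyond_closing_pair",
                                                "hanging_end"),
                           suspect_threshold = 15L,
                           snp_flag_filter = c("all", "common_only"),
                           robust_only = FALSE, seed = 1L,
                           simulate = cohortSpec()) {
  cfg <- list(hairpin_fasta = hairpin_fasta, structures = structures,
              matures = matures, snps = snps, branchpoints = branchpoints,
              rates = rates, mirtron_ids = mirtron_ids,
              robust_ids = robust_ids, disease_ids = disease_ids,
              outdir = outdir, flank_width = as.integer(flank_width),
              overhang_variant = match.arg(overhang_variant),
              suspect_threshold = as.integer(suspect_threshold),
              snp_flag_filter = match.arg(snp_flag_filter),
              robust_only = isTRUE(robust_only), seed = as.integer(seed),
              simulate = simulate)
  if (cfg$flank_width < 0L) stop("usage error: flank_width must be >= 0")
  if (cfg$suspect_threshold < 0L)
    stop("usage error: suspect_threshold must be >= 0")
  class(cfg) <- "RunConfig"
  cfg
}

conventionHeader <- function(cfg) {
  c("# coordinate_base=1 inclusive hairpin-relative",
    "# overhang_sign=positive_is_3prime_overhang canonical=(+2,+2)",
    paste0("# overhang_variant=", cfg$overhang_variant),
    "# distance_tie_rule=outside_positive_wins",
    "# bp_offset=0_is_last_intron_nucleotide d_loop=first_nt_after_loop_is_1",
    paste0("# flank_width=", cfg$flank_width,
           " suspect_threshold=", cfg$suspect_threshold,
           " snp_flag_filter=", cfg$snp_flag_filter,
           " robust_only=", cfg$robust_only,
           " seed=", cfg$seed))
}

writeReportTsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(conventionHeader(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeReportJson <- function(x, path, cfg) {
  x <- c(list(conventions = conventionHeader(cfg)), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

loadConfiguredHairpins <- function(cfg) {
  if (is.null(cfg$hairpin_fasta) || is.null(cfg$structures))
    stop("usage error: subcommand needs --hairpin_fasta and --structures")
  tags <- list()
  mirtronIds <- if (!is.null(cfg$mirtron_ids)) loadIdList(cfg$mirtron_ids)
                else character(0L)
  if (length(mirtronIds)) tags$mirtron <- mirtronIds
  if (!is.null(cfg$disease_ids)) tags$disease <- loadIdList(cfg$disease_ids)
  if (!is.null(cfg$robust_ids)) tags$robust <- loadIdList(cfg$robust_ids)
  set <- loadHairpins(cfg$hairpin_fasta, cfg$structures, cfg$matures,
                      tags = if (length(tags)) tags else NULL)
  if (cfg$robust_only) {
    if (is.null(cfg$robust_ids))
      stop("usage error: robust_only needs --robust_ids")
    set <- set[hairpinId(set) %in% tags$robust]
  }
  message("loaded ", length(set), " hairpins (",
          nrow(excludedRecords(set)), " excluded)")
  list(set = set, mirtron_ids = mirtronIds,
       disease_ids = if (!is.null(tags$disease)) tags$disease
                     else character(0L))
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages over the configured inputs and writes
#' plot-ready TSV/JSON reports into `config$outdir`. Subcommands:
#' `simulate` (emit a synthetic cohort in the exact input dialects plus a
#' truth JSON), `overhangs`, `distances`, `unf`, `snp-density`,
#' `disease-occurrence`, `branchpoints`, `fit-independence`, and `all`.
#' Counts at every filter step are reported via `message()`.
#'
#' @param subcommand One of the stage names above.
#' @param config A `RunConfig` from [pipelineConfig()].
#' @return Invisibly, a named character vector of report paths.
#' @export
runPipeline <- function(subcommand = c("simulate", "overhangs", "distances",
                                       "unf", "snp-density",
                                       "disease-occurrence", "branchpoints",
                                       "fit-independence", "all"),
                        config = pipelineConfig()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  pth <- function(f) file.path(config$outdir, f)

  if (subcommand == "simulate") {
    sim <- generateHairpinSet(config$simulate)
    set <- sim$hairpins
    writeHairpinFiles(set, pth("hairpins.fa"), pth("structures.tsv"),
                      pth("matures.tsv"))
    snps <- generateSnps(set, config$simulate$snp_rates,
                         flank_width = config$simulate$flank_width,
                         common_fraction = config$simulate$common_fraction,
                         mirtron_multiplier =
                           config$simulate$mirtron_snp_multiplier,
                         disease_multiplier =
                           config$simulate$disease_snp_multiplier,
                         seed = config$simulate$seed + 1L)
    utils::write.table(snps, pth("snps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mir <- set[vapply(as.list(set), function(r)
      "mirtron" %in% hairpinTags(r), logical(1L))]
    bps <- generateBranchpoints(mir, config$simulate$bp_offsets,
                                seed = config$simulate$seed + 2L)
    utils::write.table(bps, pth("branchpoints.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(sim$truth$id[sim$truth$mirtron], pth("mirtron_ids.txt"))
    writeLines(sim$truth$id[sim$truth$disease], pth("disease_ids.txt"))
    jsonlite::write_json(sim$truth, pth("truth.json"), digits = NA)
    message("simulated ", length(set), " hairpins, ", nrow(snps),
            " SNPs, ", nrow(bps), " branchpoints")
    return(invisible(c(out, simulate = config$outdir)))
  }

  inp <- loadConfiguredHairpins(config)
  set <- inp$set

  runStage <- function(name) {
    switch(name,
      overhangs = {
        tab <- overhangTable(set, config$overhang_variant,
                             config$suspect_threshold)
        message("duplexes formed: ", nrow(tab), "; skipped: ",
                nrow(attr(tab, "skipped")))
        if (!nrow(tab)) warning("no duplexes formed (single-mature dataset?)")
        names(tab)[names(tab) == "basal"] <- "basal_overhang"
        names(tab)[names(tab) == "apical"] <- "apical_overhang"
        out["overhangs"] <<- writeReportTsv(tab, pth("overhangs.tsv"), config)
      },
      distances = {
        d <- endDistanceTable(set)
        message("ends considered: ", sum(!is.na(d$d)), " of ", nrow(d))
        out["distances"] <<- writeReportTsv(d, pth("distances.tsv"), config)
      },
      unf = {
        u5 <- unfProfile(set, "five_prime", config$flank_width)
        u3 <- unfProfile(set, "three_prime", config$flank_width)
        u <- rbind(cbind(arm = "five_prime", u5),
                   cbind(arm = "three_prime", u3))
        out["unf"] <<- writeReportTsv(u, pth("unf.tsv"), config)
        if (!is.null(config$rates)) {
          rates <- loadRateTable(config$rates)
          corr <- correlateUnfSubstitution(u5, rates)
          out["unf_correlation"] <<- writeReportJson(
            list(rho = corr$rho, p_value = corr$p_value, n = corr$n,
                 points = corr$points),
            pth("unf_correlation.json"), config)
        }
      },
      `snp-density` = {
        if (is.null(config$snps)) stop("usage error: needs --snps")
        snps <- loadSnpTable(config$snps)
        parts <- regionPartitions(set, config$flank_width)
        dens <- snpDensity(snps, parts, config$snp_flag_filter)
        out["snp_density"] <<- writeReportTsv(dens, pth("snp_density.tsv"),
                                              config)
      },
      `disease-occurrence` = {
        if (is.null(config$snps)) stop("usage error: needs --snps")
        snps <- loadSnpTable(config$snps)
        occ <- snpOccurrenceByDisease(snps, set, inp$disease_ids,
                                      flag_filter = config$snp_flag_filter)
        out["disease_occurrence"] <<- writeReportJson(
          list(groups = occ), pth("disease_occurrence.json"), config)
      },
      branchpoints = {
        if (is.null(config$branchpoints))
          stop("usage error: needs --branchpoints")
        bps <- loadBranchpointTable(config$branchpoints)
        stats <- bpOffsetStats(bps)
        loc <- locateBranchpoints(bps, set)
        out["branchpoints"] <<- writeReportTsv(loc, pth("branchpoints.tsv"),
                                               config)
        out["bp_offsets"] <<- writeReportJson(
          list(fraction_in_window = stats$fraction_in_window, n = stats$n,
               window = stats$window, by_group = stats$by_group),
          pth("bp_offsets.json"), config)
      },
      `fit-independence` = {
        tab <- overhangTable(set, config$overhang_variant,
                             config$suspect_threshold)
        nc <- restrictNearCanonical(tab)
        fit <- fitIndependenceModel(nearCanonicalCounts(tab))
        corrAll <- if (nrow(tab) >= 3L)
          tryCatch(rankCorrelation(tab$basal, tab$apical),
                   error = function(e) NULL) else NULL
        corrNc <- if (nrow(nc$subset) >= 3L)
          tryCatch(rankCorrelation(nc$subset$basal, nc$subset$apical),
                   error = function(e) NULL) else NULL
        out["independence"] <<- writeReportJson(list(
          n_duplexes = nrow(tab),
          near_canonical_fraction = nc$fraction,
          p_short = fit$p_short, p_long = fit$p_long,
          log_likelihood = fit$log_likelihood,
          expected = fit$expected, obs_over_exp = fit$obs_over_exp,
          gof = fit$gof,
          rho_all = if (!is.null(corrAll)) corrAll$rho else NA,
          p_all = if (!is.null(corrAll)) corrAll$p_value else NA,
          rho_near_canonical = if (!is.null(corrNc)) corrNc$rho else NA,
          p_near_canonical = if (!is.null(corrNc)) corrNc$p_value else NA),
          pth("independence.json"), config)
      })
  }
  stages <- if (subcommand == "all") {
    s <- c("overhangs", "distances", "unf", "fit-independence")
    if (!is.null(config$snps)) s <- c(s, "snp-density", "disease-occurrence")
    if (!is.null(config$branchpoints)) s <- c(s, "branchpoints")
    s
  } else subcommand
  for (s in stages) runStage(s)
  invisible(out)
}
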