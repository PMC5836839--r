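#' Load hairpins from FASTA + dot-bracket structures + mature coordinates
#'
#' Assembles validated [HairpinRecord-class] objects from the three standard
#' inputs: a FASTA file of hairpin sequences, a structure file (either a
#' two-column `id<TAB>dot-bracket` table or Vienna two-line format), and a
#' tab-separated mature table with columns `id`, `mature_id`, `start`, `end`
#' (1-based, hairpin-relative, inclusive).
#'
#' Records are rejected (not fatal) when the sequence contains characters
#' outside `A`/`C`/`G`/`U` after `T`->`U` normalisation, when more than two
#' matures are annotated, when the structure is missing or its length does
#' not match the sequence, or when any record invariant fails; rejected ids
#' and reasons are available via [excludedRecords()].
#'
#' @param fasta Path to the hairpin FASTA file.
#' @param structures Path to the structure file.
#' @param matures Path to the mature coordinate TSV (optional; `NULL` loads
#'   hairpins without mature annotations).
#' @param tags Optional named list of id vectors; each hairpin whose id
#'   occurs in element `nm` receives tag `nm` (e.g.
#'   `list(mirtron = mirtronIds)`).
#' @return A [HairpinSet-class].
#' @export
loadHairpins <- function(fasta, structures, matures = NULL, tags = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  seqChar <- normalizeRna(as.character(seqs))
  names(seqChar) <- ids
  structs <- readStructureFile(structures)
  matTab <- if (is.null(matures)) NULL else
    utils::read.delim(matures, stringsAsFactors = FALSE)
  records <- list()
  excluded <- list()
  reject <- function(id, reason)
    excluded[[length(excluded) + 1L]] <<- data.frame(
      id = id, reason = reason, stringsAsFactors = FALSE)
  for (id in ids) {
    s <- seqChar[[id]]
    if (!grepl("^[ACGU]+$", s)) { reject(id, "non-canonical nucleotide"); next }
    if (is.na(structs[id])) { reject(id, "missing structure"); next }
    if (nchar(structs[[id]]) != nchar(s)) {
      reject(id, "structure length mismatch"); next
    }
    m <- NULL
    if (!is.null(matTab)) {
      m <- matTab[matTab$id == id, , drop = FALSE]
      if (nrow(m) > 2L) { reject(id, "more than two matures"); next }
      m <- if (nrow(m)) data.frame(start = m$start, end = m$end) else NULL
    }
    rec <- tryCatch(
      HairpinRecord(id, s, structure = structs[[id]], matures = m),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) { reject(id, rec); next }
    records[[id]] <- rec
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else NULL
  set <- HairpinSet(records, excluded = excluded)
  if (!is.null(tags)) set <- applyTags(set, tags)
  set
}

readStructureFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[[1L]], ">")) {
    # Vienna two-line format: >id / sequence? or structure on next line(s).
    hdr <- which(startsWith(lines, ">"))
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    out <- vapply(seq_along(hdr), function(k) {
      block <- lines[(hdr[k] + 1L):(if (k < length(hdr)) hdr[k + 1L] - 1L
                                    else length(lines))]
      db <- block[grepl("^[().]+", block)]
      if (!length(db)) return(NA_character_)
      sub("\\s.*$", "", db[[length(db)]])
    }, character(1L))
    names(out) <- ids
    out
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]]
                  else NA_character_, character(1L))
    names(out) <- vapply(parts, `[[`, character(1L), 1L)
    out
  }
}

applyTags <- function(set, tags) {
  stopifnot(is.list(tags), !is.null(names(tags)))
  recs <- lapply(set@records, function(r) {
    add <- names(tags)[vapply(tags, function(v) r@id %in% v, logical(1L))]
    if (length(add)) r@tags <- unique(c(r@tags, add))
    r
  })
  HairpinSet(recs, excluded = set@excluded)
}

#' Write a HairpinSet back to the input file dialects
#'
#' Emits a FASTA file, an `id<TAB>dot-bracket` structure table and a mature
#' TSV that round-trip through [loadHairpins()].
#'
#' @param set A [HairpinSet-class].
#' @param fasta,structures,matures Output paths (any may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeHairpinFiles <- function(set, fasta = NULL, structures = NULL,
                              matures = NULL) {
  recs <- recordList(set)
  if (!is.null(fasta)) {
    x <- Biostrings::BStringSet(vapply(recs, hairpinSeq, character(1L)))
    names(x) <- vapply(recs, hairpinId, character(1L))
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(structures)) {
    writeLines(vapply(recs, function(r) paste(r@id,
      pairingToDotBracket(r@pairing), sep = "\t"), character(1L)), structures)
  }
  if (!is.null(matures)) {
    rows <- lapply(recs, function(r) {
      m <- r@matures
      if (!nrow(m)) return(NULL)
      data.frame(id = r@id,
                 mature_id = paste0(r@id, "-",
                                    ifelse(m$arm == "five_prime", "5p", "3p")),
                 start = m$start, end = m$end, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    if (is.null(tab))
      tab <- data.frame(id = character(0L), mature_id = character(0L),
                        start = integer(0L), end = integer(0L))
    utils::write.table(tab, matures, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta = fasta, structures = structures, matures = matures))
}

#' Partition hairpins into the four study datasets
#'
#' Splits a [HairpinSet-class] into: all animal hairpins; animals excluding
#' human and mouse; human+mouse non-mirtrons; and human+mouse mirtrons.
#' Mirtron membership comes from `mirtronIds`; ids in that list that match
#' no loaded hairpin are reported as orphans.
#'
#' @param set A [HairpinSet-class].
#' @param mirtronIds Character vector of mirtron hairpin ids.
#' @param humanMousePrefixes Species prefixes treated as human/mouse.
#' @return A list with elements `all_animal`, `animal_minus_hs_mm`,
#'   `hs_mm_non_mirtrons`, `hs_mm_mirtrons` (each a `HairpinSet`) and
#'   `orphans` (character).
#' @export
partitionDatasets <- function(set, mirtronIds = character(0L),
                              humanMousePrefixes = c("hsa", "mmu")) {
  sp <- hairpinSpecies(set)
  ids <- hairpinId(set)
  hsmm <- sp %in% humanMousePrefixes
  isMir <- ids %in% mirtronIds
  tagOne <- function(idx, tag = NULL) {
    recs <- set@records[idx]
    if (!is.null(tag))
      recs <- lapply(recs, function(r) { r@tags <- unique(c(r@tags, tag)); r })
    HairpinSet(recs, excluded = set@excluded)
  }
  list(all_animal = set,
       animal_minus_hs_mm = tagOne(!hsmm),
       hs_mm_non_mirtrons = tagOne(hsmm & !isMir, "non_mirtron"),
       hs_mm_mirtrons = tagOne(hsmm & isMir, "mirtron"),
       orphans = setdiff(mirtronIds, ids))
}

#' Load an auxiliary table
#'
#' Reads one of the tab-separated side tables the pipeline consumes:
#' \describe{
#'   \item{`snp`}{columns `hairpin_id`, `position` (1-based within the
#'     hairpin; values <= 0 or > hairpin length denote flanks), `maf`,
#'     `flag` (`common` / `rare`). A missing `flag` is derived from `maf`
#'     (common = minor allele frequency > 0.01).}
#'   \item{`branchpoint`}{columns `intron_id`, `bp_offset_from_3ss`
#'     (0 = the intron's last nucleotide) and optional `hairpin_id`,
#'     `bp_hairpin_position`.}
#'   \item{`rates`}{columns `position`, `rate` (relative substitution
#'     rate, dimensionless); returned as a named numeric vector.}
#'   \item{`idlist`}{one id per line; returned de-duplicated.}
#' }
#' Malformed rows are skipped with a warning.
#'
#' @param kind One of `"snp"`, `"branchpoint"`, `"rates"`, `"idlist"`.
#' @param path File path.
#' @return A `data.frame`, named numeric vector or character vector,
#'   depending on `kind`.
#' @export
loadAuxTable <- function(kind = c("snp", "branchpoint", "rates", "idlist"),
                         path) {
  kind <- match.arg(kind)
  switch(kind,
    snp = loadSnpTable(path),
    branchpoint = loadBranchpointTable(path),
    rates = loadRateTable(path),
    idlist = loadIdList(path))
}

#' @rdname loadAuxTable
#' @export
loadSnpTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("hairpin_id", "position")
  if (!all(need %in% names(tab)))
    stop("SNP table must have columns hairpin_id, position")
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- is.na(pos) | is.na(tab$hairpin_id) | !nzchar(tab$hairpin_id)
  if (is.null(tab$flag)) {
    if (is.null(tab$maf)) stop("SNP table needs a 'flag' or 'maf' column")
    tab$flag <- ifelse(suppressWarnings(as.numeric(tab$maf)) > 0.01,
                       "common", "rare")
  }
  bad <- bad | !(tab$flag %in% c("common", "rare"))
  if (any(bad))
    warning(sum(bad), " malformed SNP row(s) skipped")
  out <- data.frame(hairpin_id = tab$hairpin_id[!bad], position = pos[!bad],
                    maf = if (is.null(tab$maf)) NA_real_ else
                      suppressWarnings(as.numeric(tab$maf))[!bad],
                    flag = tab$flag[!bad], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname loadAuxTable
#' @export
loadBranchpointTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("intron_id", "bp_offset_from_3ss")
  if (!all(need %in% names(tab)))
    stop("branchpoint table must have columns intron_id, bp_offset_from_3ss")
  off <- suppressWarnings(as.integer(tab$bp_offset_from_3ss))
  bad <- is.na(off) | off < 0L
  if (any(bad)) warning(sum(bad), " malformed branchpoint row(s) skipped")
  out <- data.frame(
    intron_id = tab$intron_id[!bad],
    bp_offset_from_3ss = off[!bad],
    hairpin_id = if (is.null(tab$hairpin_id)) NA_character_ else
      tab$hairpin_id[!bad],
    bp_hairpin_position = if (is.null(tab$bp_hairpin_position))
      NA_integer_ else
      suppressWarnings(as.integer(tab$bp_hairpin_position))[!bad],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname loadAuxTable
#' @export
loadRateTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "rate") %in% names(tab)))
    stop("rates table must have columns position, rate")
  rate <- suppressWarnings(as.numeric(tab$rate))
  bad <- is.na(rate)
  if (any(bad)) warning(sum(bad), " malformed rate row(s) skipped")
  stats::setNames(rate[!bad], tab$position[!bad])
}

#' @rdname loadAuxTable
#' @export
loadIdList <- function(path) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  ndup <- sum(duplicated(ids))
  if (ndup) message(ndup, " duplicate id(s) removed")
  unique(ids)
}

#' Match auxiliary-table ids against a HairpinSet
#'
#' @param set A [HairpinSet-class].
#' @param ids Character vector of ids referenced by a side table.
#' @return Character vector of ids with no matching hairpin (orphans).
#' @export
orphanIds <- function(set, ids) setdiff(unique(ids), hairpinId(set))
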