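#' Accessors for HairpinRecord and HairpinSet
#'
#' `hairpinId`, `hairpinSpecies`, `hairpinSeq`, `hairpinPairing`,
#' `hairpinMatures` and `hairpinTags` extract the corresponding component;
#' on a [HairpinSet-class] they vectorise over records (returning a list for
#' the non-scalar components). `excludedRecords` returns the table of inputs
#' rejected at load time.
#'
#' @param x A [HairpinRecord-class] or [HairpinSet-class].
#' @name hairpin-accessors
NULL

#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinId", function(x) standardGeneric("hairpinId"))
#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinSpecies", function(x) standardGeneric("hairpinSpecies"))
#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinSeq", function(x) standardGeneric("hairpinSeq"))
#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinPairing", function(x) standardGeneric("hairpinPairing"))
#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinMatures", function(x) standardGeneric("hairpinMatures"))
#' @rdname hairpin-accessors
#' @export
setGeneric("hairpinTags", function(x) standardGeneric("hairpinTags"))
#' @rdname hairpin-accessors
#' @export
setGeneric("excludedRecords", function(x) standardGeneric("excludedRecords"))

setMethod("hairpinId", "HairpinRecord", function(x) x@id)
setMethod("hairpinSpecies", "HairpinRecord", function(x) x@species)
setMethod("hairpinSeq", "HairpinRecord", function(x) x@sequence)
setMethod("hairpinPairing", "HairpinRecord", function(x) x@pairing)
setMethod("hairpinMatures", "HairpinRecord", function(x) x@matures)
setMethod("hairpinTags", "HairpinRecord", function(x) x@tags)

setMethod("hairpinId", "HairpinSet",
  function(x) vapply(x@records, hairpinId, character(1L)))
setMethod("hairpinSpecies", "HairpinSet",
  function(x) vapply(x@records, hairpinSpecies, character(1L)))
setMethod("hairpinSeq", "HairpinSet",
  function(x) vapply(x@records, hairpinSeq, character(1L)))
setMethod("hairpinPairing", "HairpinSet",
  function(x) lapply(x@records, hairpinPairing))
setMethod("hairpinMatures", "HairpinSet",
  function(x) lapply(x@records, hairpinMatures))
setMethod("hairpinTags", "HairpinSet",
  function(x) lapply(x@records, hairpinTags))
setMethod("excludedRecords", "HairpinSet", function(x) x@excluded)

#' @export
setMethod("length", "HairpinSet", function(x) length(x@records))
#' @export
setMethod("names", "HairpinSet", function(x) names(x@records))

#' @export
setMethod("[[", "HairpinSet", function(x, i) x@records[[i]])

#' @export
setMethod("[", "HairpinSet", function(x, i, j, ..., drop = TRUE) {
  HairpinSet(x@records[i], excluded = x@excluded)
})

#' Coerce a HairpinSet to a plain list of records
#' @param x A [HairpinSet-class].
#' @param ... Ignored.
#' @export
setMethod("as.list", "HairpinSet", function(x, ...) x@records)

#' @export
setMethod("show", "HairpinRecord", function(object) {
  m <- object@matures
  cat("HairpinRecord ", object@id, " (", object@species, "), ",
      nchar(object@sequence), " nt, ",
      sum(!is.na(object@pairing)) / 2, " bp, ",
      nrow(m), " mature(s)", sep = "")
  if (length(object@tags))
    cat(" [", paste(object@tags, collapse = ","), "]", sep = "")
  cat("\n  ", object@sequence, "\n  ",
      pairingToDotBracket(object@pairing), "\n", sep = "")
  if (nrow(m))
    cat(paste0("  ", m$arm, ": [", m$start, ", ", m$end, "]",
               collapse = "\n"), "\n")
})

#' @export
setMethod("show", "HairpinSet", function(object) {
  cat("HairpinSet of", length(object@records), "hairpins")
  sp <- table(hairpinSpecies(object))
  if (length(sp))
    cat(" (", paste0(names(sp), ":", sp, collapse = " "), ")", sep = "")
  cat(";", nrow(object@excluded), "excluded\n")
})

# internal: records of a set as a list, accepting either container
recordList <- function(x) {
  if (is(x, "HairpinSet")) x@records
  else if (is(x, "HairpinRecord")) list(x)
  else if (is.list(x)) x
  else stop("expected a HairpinSet, HairpinRecord or list of records")
}
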