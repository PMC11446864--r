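# Fragment registry and triage: field-collection provenance (sector, bag),
# operator-supplied anatomical classification, and the length-based retention
# rule applied before re-association.

BONE_TYPES <- c("diaphysis", "flat_bone", "epiphysis_short")
REGIONS <- c("head", "trunk", "upper_limb", "lower_limb")

#' Build and validate a fragment registry
#'
#' One row per collected fragment: identity, source model file, collection
#' provenance (grid sector, bag), operator-supplied anatomical class, and the
#' measured maximum length. The `retained` flag is recomputed from the
#' retention rule (length >= `min_length`; fragments under 2 cm are excluded
#' from re-association).
#'
#' @param df data.frame with columns `id`, `source`, `sector`, `bag`,
#'   `bone_type` (one of diaphysis, flat_bone, epiphysis_short), `region`
#'   (head, trunk, upper_limb, lower_limb), optional `bone_name`, `length_mm`
#' @param min_length retention threshold, mm (default 20)
#' @return a validated `fragment_registry` data.frame with `retained` set
#' @export
fragment_registry <- function(df, min_length = 20) {
  req <- c("id", "bone_type", "region", "length_mm")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate fragment id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- !df$bone_type %in% BONE_TYPES
  if (any(bad))
    stop("record '", df$id[which(bad)[1]], "': unknown bone_type '",
         df$bone_type[which(bad)[1]], "' (expected ",
         paste(BONE_TYPES, collapse = ", "), ")")
  bad <- !df$region %in% REGIONS
  if (any(bad))
    stop("record '", df$id[which(bad)[1]], "': unknown region '",
         df$region[which(bad)[1]], "' (expected ",
         paste(REGIONS, collapse = ", "), ")")
  if (!is.numeric(df$length_mm) || anyNA(df$length_mm))
    stop("length_mm must be numeric and complete")
  if (is.null(df$bone_name)) df$bone_name <- NA_character_
  df$retained <- df$length_mm >= min_length
  attr(df, "min_length") <- min_length
  class(df) <- c("fragment_registry", "data.frame")
  df
}

#' Triage a registry into candidate matching pools
#'
#' Retained fragments are grouped hierarchically — bone type, then anatomical
#' region, then bone name where the operator supplied one. Match plans should
#' only pair fragments within the same innermost non-empty group. The
#' grouping depends only on record content, not row order.
#'
#' @param registry a `fragment_registry`
#' @return named list of character vectors of fragment ids (sorted); names
#'   are `bone_type/region` or `bone_type/region/bone_name`
#' @export
triage <- function(registry) {
  stopifnot(inherits(registry, "fragment_registry"))
  r <- registry[registry$retained, , drop = FALSE]
  if (nrow(r) == 0) return(list())
  key <- ifelse(is.na(r$bone_name) | r$bone_name == "",
                paste(r$bone_type, r$region, sep = "/"),
                paste(r$bone_type, r$region, r$bone_name, sep = "/"))
  pools <- split(r$id, key)
  pools <- lapply(pools, sort)
  pools[order(names(pools))]
}

#' Retention bookkeeping for a triage
#'
#' @param n_retained,n_total fragment counts (retained after the length rule,
#'   and collected in total)
#' @return list with the counts and `percent` retained (unrounded)
#' @export
retention_summary <- function(n_retained, n_total) {
  if (n_retained > n_total) stop("retained count exceeds total")
  list(n_retained = n_retained, n_total = n_total,
       percent = 100 * n_retained / n_total)
}

#' Read / write a fragment registry as CSV
#'
#' Round-trips losslessly through CSV.
#'
#' @param path a `.csv` file
#' @param min_length retention threshold passed to [fragment_registry()]
#' @return [load_registry()] returns a `fragment_registry`
#' @export
load_registry <- function(path, min_length = 20) {
  fragment_registry(utils::read.csv(path, stringsAsFactors = FALSE),
                    min_length = min_length)
}

#' @rdname load_registry
#' @param registry a `fragment_registry`
#' @export
save_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}
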