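# The standard covariate ledger: which annotation categories are partialled
# out when testing each annotation of interest.

.defaultGroups <- c(
  low_level_visual = "visual",
  alexnet_l1 = "visual", alexnet_l2 = "visual", alexnet_l3 = "visual",
  alexnet_l4 = "visual", alexnet_l5 = "visual", alexnet_l6 = "visual",
  alexnet_l7 = "visual", alexnet_l8 = "visual",
  shots = "visual",
  small_locations = "locations", large_locations = "locations",
  mfcc = "low_level_audio",
  speech = "mid_level_audio",
  events = "conceptual"
)

#' The standard covariate ledger
#'
#' Encodes the default choice of covariates per annotation of interest: an
#' annotation is corrected for every category outside its own group, and
#' never for categories inside its group (which share the same relevant
#' information, e.g. small- and large-scale locations are nested).  Shots
#' appear only as covariates, never as an annotation of interest.
#'
#' The default category set is: `low_level_visual`, `alexnet_l1` ...
#' `alexnet_l8`, `shots` (group `visual`); `small_locations`,
#' `large_locations` (group `locations`); `mfcc` (`low_level_audio`);
#' `speech` (`mid_level_audio`); `events` (`conceptual`).
#'
#' @param categories restrict the ledger to these categories (both as
#'   annotations of interest and as covariates); defaults to all.
#' @return A [CovariateLedger-class].
#' @examples
#' covariatesFor(defaultCovariateLedger(), "small_locations")
#' @export
defaultCovariateLedger <- function(categories = names(.defaultGroups)) {
  groups <- .defaultGroups[intersect(names(.defaultGroups), categories)]
  interest <- setdiff(names(groups), "shots")
  map <- lapply(interest, function(cat) {
    unname(setdiff(names(groups)[groups != groups[[cat]]], cat))
  })
  names(map) <- interest
  new("CovariateLedger", map = map, groups = groups)
}

#' Build a custom covariate ledger
#'
#' @param map named list: category of interest -> character vector of
#'   covariate categories.
#' @param groups named character: category -> group label, covering every
#'   category appearing in `map`.
#' @return A validated [CovariateLedger-class]; construction fails if any
#'   category covaries for itself or for a same-group category.
#' @export
covariateLedger <- function(map, groups) {
  new("CovariateLedger", map = map, groups = groups)
}

#' Covariates for an annotation category
#'
#' @param ledger a [CovariateLedger-class].
#' @param category annotation of interest.
#' @param available optionally restrict to these category names (covariates
#'   not available in a given dataset are dropped).
#' @return Character vector of covariate categories.
#' @export
covariatesFor <- function(ledger, category, available = NULL) {
  stopifnot(is(ledger, "CovariateLedger"))
  if (!category %in% names(ledger@map)) {
    stopf("category '%s' is not an annotation of interest in this ledger",
          category)
  }
  covs <- ledger@map[[category]]
  if (!is.null(available)) covs <- intersect(covs, available)
  covs
}
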