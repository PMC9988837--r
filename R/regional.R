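# Regional cohort construction from admixture proportions: maximum-proportion
# labeling, median-threshold filtering within each region, and balanced
# random subsampling to a fixed per-region size.

#' Assign each individual to its maximum-proportion region
#'
#' Labels each individual with the region of its largest admixture
#' proportion. Ties are broken deterministically towards the lowest column
#' index.
#'
#' @param q `n x R` admixture matrix (rows sum to 1), ids in rownames.
#' @param region_names Region labels, one per Q column; defaults to
#'   `colnames(q)`.
#' @return Object of class `regional_assignment`: data.frame with `id`,
#'   `region`, `max_proportion`, `selected` (all TRUE at this stage) plus
#'   attributes `region_names` and `region_medians` (filled by
#'   [median_threshold_filter()]).
#' @export
assign_max_region <- function(q, region_names = colnames(q)) {
  if (is.null(dim(q)) || nrow(q) == 0L) stop("empty Q matrix")
  if (is.null(region_names)) stop("region names required")
  if (length(region_names) != ncol(q))
    stop("expected ", ncol(q), " region names, got ", length(region_names))
  ids <- rownames(q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(q)))
  # max.col(ties.method = "first") = argmax with lowest-index tie-break
  widx <- max.col(q, ties.method = "first")
  out <- data.frame(id = ids,
                    region = factor(region_names[widx],
                                    levels = region_names),
                    max_proportion = q[cbind(seq_len(nrow(q)), widx)],
                    selected = TRUE, stringsAsFactors = FALSE)
  attr(out, "region_names") <- region_names
  class(out) <- c("regional_assignment", "data.frame")
  out
}

#' Filter each region by its median maximum proportion
#'
#' Within each region, computes the median of the members' maximum ancestry
#' proportions and keeps individuals whose maximum proportion is greater than
#' or equal to that median (the boundary is inclusive). The even-count median
#' is the midpoint of the two central values.
#'
#' @param assignment A `regional_assignment`.
#' @return The assignment with `selected` updated and a `region_medians`
#'   attribute (named numeric).
#' @export
median_threshold_filter <- function(assignment) {
  stopifnot(inherits(assignment, "regional_assignment"))
  regions <- attr(assignment, "region_names")
  meds <- stats::setNames(rep(NA_real_, length(regions)), regions)
  sel <- assignment$selected
  for (r in regions) {
    members <- which(assignment$region == r & assignment$selected)
    if (length(members) == 0L) {
      warning("region '", r, "' has no members; median undefined, skipped")
      next
    }
    meds[[r]] <- stats::median(assignment$max_proportion[members])
    sel[members] <- assignment$max_proportion[members] >= meds[[r]]
  }
  assignment$selected <- sel
  attr(assignment, "region_medians") <- meds
  assignment
}

#' Balanced random subsample of selected individuals per region
#'
#' Draws `n_target` selected members uniformly without replacement from each
#' region; regions with at most `n_target` survivors keep all of them (as for
#' the smallest region in the emulated study). Sampling uses a seeded shuffle
#' over ids sorted lexically, so the result is independent of input row
#' order.
#'
#' @param assignment A filtered `regional_assignment`.
#' @param n_target Individuals to keep per region (default 186).
#' @param seed Integer seed.
#' @return The assignment with `selected` updated.
#' @export
balanced_subsample <- function(assignment, n_target = 186L, seed = 1L) {
  stopifnot(inherits(assignment, "regional_assignment"))
  if (n_target <= 0L) stop("n_target must be positive")
  regions <- attr(assignment, "region_names")
  sel <- assignment$selected
  for (k in seq_along(regions)) {
    members <- which(assignment$region == regions[k] & assignment$selected)
    if (length(members) <= n_target) next
    ord <- members[order(assignment$id[members])]
    set.seed(derive_seed(seed, k))
    keep <- ord[sample.int(length(ord), n_target)]
    sel[setdiff(members, keep)] <- FALSE
  }
  assignment$selected <- sel
  assignment
}

#' @export
print.regional_assignment <- function(x, ...) {
  cat("Regional assignment:", nrow(x), "individuals\n")
  tab <- table(region = x$region, selected = x$selected)
  print(tab)
  meds <- attr(x, "region_medians")
  if (!is.null(meds)) {
    cat("Region medians of max proportion:\n")
    print(round(meds, 4))
  }
  invisible(x)
}
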