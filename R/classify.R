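#' Morphological activation classes
#'
#' @return Character vector of the three activation-state labels.
#' @export
morph_class_levels <- function() c("branched", "amoeboid", "transitional")

#' Rule set for activation-state classification
#'
#' Thresholds on sphericity (S), process number (NP), total process length
#' (TL, um) and surface area (A, um^2). A cell is "branched" when at least
#' `min_criteria` of `S < 0.5`, `NP > 7`, `TL > 140`, `A > 2400` hold;
#' "amoeboid" when at least `min_criteria` of `S > 0.7`, `NP < 3`,
#' `TL < 60`, `A < 1500` hold; otherwise "transitional". All comparisons
#' are strict. Volume is carried in the morphology vector but unused by the
#' default rule.
#'
#' @param branched named thresholds `c(S=, NP=, TL=, A=)` (exceed-below for
#'   S, exceed-above otherwise).
#' @param amoeboid named thresholds `c(S=, NP=, TL=, A=)`.
#' @param min_criteria criteria required for a call (1-4).
#' @return A `classifier_rule` object.
#' @export
classifier_rule <- function(branched = c(S = 0.5, NP = 7, TL = 140, A = 2400),
                            amoeboid = c(S = 0.7, NP = 3, TL = 60, A = 1500),
                            min_criteria = 3L) {
  need <- c("S", "NP", "TL", "A")
  if (!all(need %in% names(branched)) || !all(need %in% names(amoeboid)))
    stop("rule thresholds must be named S, NP, TL, A")
  if (min_criteria < 1 || min_criteria > 4)
    stop("`min_criteria` must be in 1..4")
  if (branched[["S"]] > amoeboid[["S"]] || branched[["NP"]] < amoeboid[["NP"]] ||
      branched[["TL"]] < amoeboid[["TL"]] || branched[["A"]] < amoeboid[["A"]])
    stop("branched and amoeboid intervals must be disjoint per parameter")
  structure(list(branched = branched[need], amoeboid = amoeboid[need],
                 min_criteria = as.integer(min_criteria)),
            class = "classifier_rule")
}

# criteria counts for vectors of parameters; returns a list of two counts
criteria_counts <- function(S, NP, TL, A, rule) {
  nb <- (S < rule$branched[["S"]]) + (NP > rule$branched[["NP"]]) +
    (TL > rule$branched[["TL"]]) + (A > rule$branched[["A"]])
  na_ <- (S > rule$amoeboid[["S"]]) + (NP < rule$amoeboid[["NP"]]) +
    (TL < rule$amoeboid[["TL"]]) + (A < rule$amoeboid[["A"]])
  list(branched = nb, amoeboid = na_)
}

#' Classify one cell's activation state
#'
#' @param m a [cell_morphology()] or a list/row with `sphericity`,
#'   `n_processes`, `total_length`, `surface_area` (um units).
#' @param rule a [classifier_rule()].
#' @return List with `label` and the criteria counts
#'   `n_branched_criteria`, `n_amoeboid_criteria`.
#' @export
classify_cell <- function(m, rule = classifier_rule()) {
  par <- c(S = m$sphericity, NP = m$n_processes, TL = m$total_length,
           A = m$surface_area)
  bad <- names(par)[!is.finite(par)]
  if (length(bad))
    stop("missing or non-finite parameter(s): ", paste(bad, collapse = ", "))
  ct <- criteria_counts(par[["S"]], par[["NP"]], par[["TL"]], par[["A"]], rule)
  label <- if (ct$branched >= rule$min_criteria) "branched"
  else if (ct$amoeboid >= rule$min_criteria) "amoeboid"
  else "transitional"
  list(label = label,
       n_branched_criteria = as.integer(ct$branched),
       n_amoeboid_criteria = as.integer(ct$amoeboid))
}

#' Classify a population and summarize class proportions
#'
#' @param cells list of [cell_morphology()] objects, or a data.frame with
#'   columns `sphericity`, `n_processes`, `total_length`, `surface_area`.
#' @param rule a [classifier_rule()].
#' @return List with `table` (per-cell labels and criteria counts appended)
#'   and `proportions` (named percentages over the three classes, summing
#'   to 100).
#' @export
classify_population <- function(cells, rule = classifier_rule()) {
  if (is.data.frame(cells)) {
    if (nrow(cells) == 0L) stop("empty cell table")
    rows <- lapply(seq_len(nrow(cells)), function(i) as.list(cells[i, ]))
    tab <- cells
  } else {
    if (length(cells) == 0L) stop("empty cell list")
    rows <- cells
    tab <- do.call(rbind, lapply(cells, function(m)
      data.frame(sphericity = m$sphericity, n_processes = m$n_processes,
                 total_length = m$total_length,
                 surface_area = m$surface_area)))
  }
  calls <- lapply(rows, classify_cell, rule = rule)
  tab$label <- vapply(calls, `[[`, character(1), "label")
  tab$n_branched_criteria <- vapply(calls, `[[`, integer(1),
                                    "n_branched_criteria")
  tab$n_amoeboid_criteria <- vapply(calls, `[[`, integer(1),
                                    "n_amoeboid_criteria")
  prop <- 100 * prop.table(table(factor(tab$label, morph_class_levels())))
  list(table = tab, proportions = c(prop))
}
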