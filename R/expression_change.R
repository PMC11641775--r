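#' Expression-change labels
#'
#' The eight possible interpretations of a (puncta-count direction,
#' covered-area direction) pair between two time points.
#'
#' @export
EXPRESSION_CHANGE_LABELS <- c(
  "expression_increase", "expression_decrease",
  "increase_within_existing_clusters", "decrease_within_existing_clusters",
  "dispersion", "aggregation", "no_change", "indeterminate")

#' Classify an expression change from count and area verdicts
#'
#' Interprets the joint behaviour of the two expression read-outs between two
#' time points. Concordant significant changes in both the number of
#' immunopuncta and the area covered by the protein confirm a genuine change
#' in expression level; a change in area alone means the expression change is
#' confined to pre-existing protein clusters; a change in puncta count alone
#' reflects redistribution — more puncta without more area is dispersion,
#' fewer puncta without less area is aggregation into fewer but larger
#' clusters. Opposing significant directions are flagged indeterminate.
#'
#' @param count_direction,area_direction `"up"`, `"down"` or `"ns"` — the
#'   post-hoc verdicts for the puncta count and the covered area between the
#'   two time points (see [compare_groups()]).
#' @return One of [EXPRESSION_CHANGE_LABELS]. Vectorized over both arguments.
#' @examples
#' classify_expression_change("ns", "up")    # increase_within_existing_clusters
#' classify_expression_change("down", "ns")  # aggregation
#' classify_expression_change("up", "ns")    # dispersion
#' @export
classify_expression_change <- function(count_direction, area_direction) {
  ok <- c("up", "down", "ns")
  if (!all(count_direction %in% ok) || !all(area_direction %in% ok))
    stop("directions must be 'up', 'down' or 'ns'")
  key <- paste(count_direction, area_direction, sep = ".")
  map <- c(up.up = "expression_increase",
           down.down = "expression_decrease",
           ns.up = "increase_within_existing_clusters",
           ns.down = "decrease_within_existing_clusters",
           up.ns = "dispersion",
           down.ns = "aggregation",
           ns.ns = "no_change",
           up.down = "indeterminate",
           down.up = "indeterminate")
  unname(map[key])
}
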