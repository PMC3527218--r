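# Barrel labels and the somatotopic (Row, Arc) coordinate convention.

.greek <- c("alpha", "beta", "gamma", "delta")
.rows <- c("A", "B", "C", "D", "E")

#' All 24 valid barrel labels
#'
#' The vibrissal map evaluated here comprises rows A-E crossed with arcs 1-4
#' plus the four "greek" barrels (alpha, beta, gamma, delta) that form arc 0.
#'
#' @return character vector of the 24 labels.
#' @export
barrel_labels <- function() {
  c(.greek, as.vector(outer(.rows, 1:4, paste0)))
}

is_barrel_label <- function(label) label %in% barrel_labels()

assert_barrel_label <- function(label) {
  bad <- setdiff(label, barrel_labels())
  if (length(bad)) stop("unknown barrel label(s): ", paste(bad, collapse = ", "))
  invisible(label)
}

#' Numeric (Row, Arc) coordinates of a barrel label
#'
#' Rows A-E map to 0-4 and arcs greek,1..4 map to 0..4. The greek barrels sit
#' on the arc-0 line between integer rows and are therefore assigned
#' half-integer Row coordinates (alpha 0.5, beta 1.5, gamma 2.5, delta 3.5),
#' interleaving them between the rows they border.
#'
#' @param label character vector of barrel labels.
#' @return data.frame with columns `label`, `row`, `arc`.
#' @export
numeric_row_arc <- function(label) {
  assert_barrel_label(label)
  row <- numeric(length(label)); arc <- numeric(length(label))
  g <- match(label, .greek)
  isg <- !is.na(g)
  row[isg] <- g[isg] - 0.5
  arc[isg] <- 0
  if (any(!isg)) {
    row[!isg] <- match(substr(label[!isg], 1, 1), .rows) - 1
    arc[!isg] <- as.numeric(substr(label[!isg], 2, 2))
  }
  data.frame(label = label, row = row, arc = arc, stringsAsFactors = FALSE)
}

# Label of the neighbor one step along a somatotopic direction, or NA.
# Directions: "row" = (row, arc + 1), "arc" = (row + 1, arc),
# "321" = (row + 1, arc - 1) (e.g. C3 -> D2 -> E1).
neighbor_label <- function(label, direction = c("row", "arc", "321")) {
  direction <- match.arg(direction)
  ra <- numeric_row_arc(label)
  step <- switch(direction, row = c(0, 1), arc = c(1, 0), `321` = c(1, -1))
  all_ra <- numeric_row_arc(barrel_labels())
  out <- rep(NA_character_, nrow(ra))
  for (i in seq_len(nrow(ra))) {
    hit <- which(all_ra$row == ra$row[i] + step[1] &
                   all_ra$arc == ra$arc[i] + step[2])
    if (length(hit) == 1) out[i] <- all_ra$label[hit]
  }
  out
}

#' Printed per-column parameter table (cohort means and SDs, n = 12)
#'
#' Per-barrel means and standard deviations across animals of the five
#' measured column parameters (barrel height, barrel top and bottom depth,
#' barrel area, column height and column orientation) together with the
#' derived quantities (barrel volume, column diameter, column volume).
#' Shipped as plain CSV; used as the default simulation condition.
#'
#' @return data.frame with one row per barrel label.
#' @export
barrel_parameters <- function() {
  utils::read.csv(system.file("extdata", "barrel_parameters.csv",
                              package = "barrelfield"),
                  stringsAsFactors = FALSE)
}

#' Printed per-column registration precision table
#'
#' Standard error (precision within the principal column), standard
#' deviation (precision of long-range projections in surrounding columns)
#' and leave-one-out RMSE (minimal precision) of the registered barrel
#' location, per column, in micrometers.
#'
#' @return data.frame with columns `label`, `se`, `sd`, `rmse`.
#' @export
column_precision <- function() {
  utils::read.csv(system.file("extdata", "column_precision.csv",
                              package = "barrelfield"),
                  stringsAsFactors = FALSE)
}

#' Default manual-vs-standard landmark depth offsets
#'
#' Mean differences (manual minus standard, micrometers) of traced BT, BB and
#' WM depths per column, applied by [correct_landmark_depths()]. Only the D2
#' column has published values; all other rows default to zero and can be
#' calibrated from a user's own cohort by editing the CSV.
#'
#' @return data.frame with columns `label`, `bt_offset`, `bb_offset`,
#'   `wm_offset`.
#' @export
landmark_offsets <- function() {
  utils::read.csv(system.file("extdata", "landmark_offsets.csv",
                              package = "barrelfield"),
                  stringsAsFactors = FALSE)
}
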