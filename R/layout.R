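# Second-order polynomial parameterization of the somatotopic layout:
# three maps f, g, h from discrete (Row, Arc) coordinates to the x/y/z
# coordinates of the barrel centers in the C2 frame.

layout_design <- function(row, arc) {
  cbind(c00 = 1, c10 = row, c01 = arc,
        c20 = row^2, c11 = row * arc, c02 = arc^2)
}

coef_names <- c("c00", "c10", "c01", "c20", "c11", "c02")

#' Fit the 2nd-order layout polynomials to barrel centers
#'
#' Ordinary least squares of each BC coordinate (x, y, z in the C2 frame)
#' on `(1, Row, Arc, Row^2, Row*Arc, Arc^2)`. Coefficient `cIJ` multiplies
#' `Row^I * Arc^J`; e.g. the `c01` coefficient of the x-map measures the
#' regular arc spacing and the `c10` coefficient of the x-map the deviation
#' of the layout from a rectangular grid. Constant coefficients (`c00`) are
#' fitted but excluded from comparisons, leaving 15 informative
#' coefficients.
#'
#' @param bc data.frame with columns `label`, `x`, `y`, `z` (um, C2 frame).
#' @return object of class `layout_polynomials`: `coefficients` (6 x 3
#'   matrix, columns x/y/z), `rmse` (residual 3D RMSE, um), `labels`.
#' @export
fit_layout <- function(bc) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(bc)))
  if (nrow(bc) < 6) stop("need at least 6 barrels to fit 6 coefficients")
  ra <- numeric_row_arc(bc$label)
  X <- layout_design(ra$row, ra$arc)
  if (qr(X)$rank < 6) stop("rank-deficient layout (collinear barrels)")
  Y <- as.matrix(bc[, c("x", "y", "z")])
  fit <- stats::lm.fit(X, Y)
  res <- Y - X %*% fit$coefficients
  co <- fit$coefficients
  rownames(co) <- coef_names
  structure(list(coefficients = co,
                 rmse = sqrt(mean(rowSums(res^2))),
                 labels = bc$label),
            class = "layout_polynomials")
}

#' @export
print.layout_polynomials <- function(x, ...) {
  cat("layout_polynomials over", length(x$labels), "barrels, residual RMSE",
      format(x$rmse, digits = 4), "um\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Predict barrel-center positions from layout polynomials
#'
#' @param poly a [fit_layout()] result (or a bare 6 x 3 coefficient
#'   matrix).
#' @param label barrel labels at which to evaluate the maps.
#' @return matrix (length(label) x 3) of predicted positions, um.
#' @export
predict_layout <- function(poly, label) {
  co <- if (inherits(poly, "layout_polynomials")) poly$coefficients else poly
  ra <- numeric_row_arc(label)
  out <- layout_design(ra$row, ra$arc) %*% co
  rownames(out) <- label
  out
}

#' Deviation of the standard-model coefficients in SD units
#'
#' For every non-constant coefficient: `|mean(per-animal) - standard| / SD
# (per-animal)`. A zero SD yields an infinite deviation, flagged.
#'
#' @param standard [fit_layout()] result for the standard model.
#' @param per_animal list of per-animal [fit_layout()] results (>= 3).
#' @return data.frame with columns `coefficient`, `map` (x/y/z), `mean`,
#'   `sd`, `standard`, `deviation_sd`, `flagged`.
#' @export
coefficient_deviation <- function(standard, per_animal) {
  if (length(per_animal) < 3) stop("need at least 3 animals")
  arr <- simplify2array(lapply(per_animal, function(p) p$coefficients))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  out <- expand.grid(coefficient = coef_names, map = c("x", "y", "z"),
                     stringsAsFactors = FALSE)
  out$mean <- as.vector(mu)
  out$sd <- as.vector(sdv)
  out$standard <- as.vector(standard$coefficients)
  out$deviation_sd <- abs(out$mean - out$standard) / out$sd
  out$flagged <- !is.finite(out$deviation_sd)
  out[out$coefficient != "c00", , drop = FALSE]
}

#' Leave-one-out cross validation of the layout parameterization
#'
#' For every held-out field, the layout coefficients averaged over the
#' remaining fields predict the held-out BC positions at their (Row, Arc)
#' coordinates; the root mean squared error between predicted and actual 3D
#' BC locations is reported per animal and per barrel. The C2 barrel is the
#' frame origin during parameterization, so its per-barrel RMSE is reported
#' as the average of C1 and C3.
#'
#' @param fields list of BC tables (data.frame `label`, `x`, `y`, `z`) in a
#'   common analysis frame.
#' @return list with `per_animal` (named numeric), `per_barrel` (named
#'   numeric), and `average` (mean per-animal RMSE, um).
#' @export
leave_one_out <- function(fields) {
  m <- length(fields)
  if (m < 3) stop("need at least 3 fields")
  fits <- lapply(fields, fit_layout)
  per_animal <- numeric(m)
  sq_by_barrel <- list()
  for (i in seq_len(m)) {
    arr <- simplify2array(lapply(fits[-i], function(p) p$coefficients))
    co <- apply(arr, c(1, 2), mean)
    held <- fields[[i]]
    pred <- predict_layout(co, held$label)
    err2 <- rowSums((as.matrix(held[, c("x", "y", "z")]) - pred)^2)
    per_animal[i] <- sqrt(mean(err2))
    for (k in seq_along(held$label)) {
      l <- held$label[k]
      sq_by_barrel[[l]] <- c(sq_by_barrel[[l]], err2[k])
    }
  }
  names(per_animal) <- vapply(seq_len(m), function(i)
    paste0("field", i), character(1))
  per_barrel <- vapply(sq_by_barrel, function(v) sqrt(mean(v)), numeric(1))
  if (all(c("C1", "C3") %in% names(per_barrel)))
    per_barrel["C2"] <- (per_barrel[["C1"]] + per_barrel[["C3"]]) / 2
  list(per_animal = per_animal, per_barrel = per_barrel,
       average = mean(per_animal))
}
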