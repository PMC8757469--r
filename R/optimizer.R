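#' Property surface on a two-dimensional parameter grid
#'
#' Tabulates one property (e.g. solvation free energy, first-shell radius,
#' exchange rate, activity derivative) over a grid of two parameters -- the
#' ion-water pair (`sigma_io`, `eps_io`) or the combination-rule scaling
#' pair (`lambda_sigma`, `lambda_eps`).
#'
#' @param axes Named list of two strictly increasing numeric grids.
#' @param values Matrix of property values, `length(axes[[1]])` rows by
#'   `length(axes[[2]])` columns; non-finite entries are treated as missing.
#' @param property Property label.
#' @param units Units string.
#' @return Object of class `GridSurface`.
#' @export
grid_surface <- function(axes, values, property, units = "") {
  stopifnot(length(axes) == 2, !is.null(names(axes)),
            all(vapply(axes, function(a) all(diff(a) > 0), TRUE)))
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(axes[[1]]), length(axes[[2]]))))
    stop("values matrix does not match the axes", call. = FALSE)
  structure(list(axes = axes, values = values, property = property,
                 units = units), class = "GridSurface")
}

#' @export
print.GridSurface <- function(x, ...) {
  cat(sprintf("<GridSurface> %s [%s]: %d x %d grid in (%s, %s)\n",
              x$property, x$units, length(x$axes[[1]]), length(x$axes[[2]]),
              names(x$axes)[1], names(x$axes)[2]))
  invisible(x)
}

#' @export
as.data.frame.GridSurface <- function(x, ...) {
  d <- expand.grid(i = seq_along(x$axes[[1]]), j = seq_along(x$axes[[2]]))
  out <- data.frame(a1 = x$axes[[1]][d$i], a2 = x$axes[[2]][d$j],
                    value = x$values[cbind(d$i, d$j)])
  names(out) <- c(names(x$axes), x$property)
  out[order(out[[1]], out[[2]]), , drop = FALSE]
}

#' Read and write property surfaces as TSV
#'
#' Long format: two axis columns followed by one value column named after
#' the property; every (axis1, axis2) grid combination must be present.
#'
#' @param file Path to a tab-separated file.
#' @return `read_surface_tsv()` returns a `GridSurface`.
#' @export
read_surface_tsv <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (ncol(d) != 3) stop("expected two axis columns and one value column",
                         call. = FALSE)
  a1 <- sort(unique(d[[1]])); a2 <- sort(unique(d[[2]]))
  v <- matrix(NA_real_, length(a1), length(a2))
  v[cbind(match(d[[1]], a1), match(d[[2]], a2))] <- d[[3]]
  if (anyNA(v)) stop("surface file does not cover the full grid", call. = FALSE)
  axes <- list(a1, a2); names(axes) <- names(d)[1:2]
  grid_surface(axes, v, property = names(d)[3])
}

#' @rdname read_surface_tsv
#' @param surface A `GridSurface`.
#' @export
write_surface_tsv <- function(surface, file) {
  utils::write.table(as.data.frame(surface), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Selection target for one property
#'
#' Either a two-sided target `value +- tolerance` or a one-sided/two-sided
#' bound via `lower`/`upper`.
#'
#' @param property Property label matching a surface name.
#' @param value,tolerance Central target and nonnegative two-sided
#'   tolerance.
#' @param lower,upper Bounds (inclusive) used when `value` is absent.
#' @return Object of class `TargetSpec`.
#' @export
#' @examples
#' target_spec("dG_solv", value = -2532, tolerance = 1)
#' target_spec("R_b", lower = 0.206, upper = 0.208)
target_spec <- function(property, value = NULL, tolerance = NULL,
                        lower = NULL, upper = NULL) {
  if (!is.null(value)) {
    if (is.null(tolerance) || tolerance < 0)
      stop("a central target needs a nonnegative tolerance", call. = FALSE)
    lower <- value - tolerance; upper <- value + tolerance
  } else if (is.null(lower) && is.null(upper)) {
    stop("target needs value+tolerance or bounds", call. = FALSE)
  }
  structure(list(property = property, value = value, tolerance = tolerance,
                 lower = lower %||% -Inf, upper = upper %||% Inf),
            class = "TargetSpec")
}

.surface_nodes <- function(surfaces) {
  ax <- surfaces[[1]]$axes
  for (s in surfaces[-1]) {
    if (!identical(names(s$axes), names(ax)) ||
        !isTRUE(all.equal(s$axes, ax, tolerance = 1e-12)))
      stop("surfaces are not tabulated on a common grid", call. = FALSE)
  }
  d <- expand.grid(i = seq_along(ax[[1]]), j = seq_along(ax[[2]]))
  nodes <- data.frame(a1 = ax[[1]][d$i], a2 = ax[[2]][d$j])
  names(nodes) <- names(ax)
  for (nm in names(surfaces))
    nodes[[nm]] <- surfaces[[nm]]$values[cbind(d$i, d$j)]
  # deterministic lexicographic order in the axes
  nodes[order(nodes[[1]], nodes[[2]]), , drop = FALSE]
}

#' Grid nodes passing every selection target
#'
#' Evaluates all targets at the grid nodes (no interpolation) and returns
#' the nodes passing every one, in deterministic lexicographic axis order.
#' Loosening any tolerance can only grow the feasible set.
#'
#' @param surfaces Named list of `GridSurface` objects on a common grid;
#'   names must cover every target property.
#' @param targets List of `TargetSpec` objects.
#' @return Data frame of feasible nodes (axis columns plus property
#'   columns), with attribute `diagnostics`: per-target pass counts and the
#'   full pass/fail matrix.
#' @export
feasible_set <- function(surfaces, targets) {
  stopifnot(length(surfaces) >= 1, length(targets) >= 1)
  props <- vapply(targets, `[[`, "", "property")
  miss <- setdiff(props, names(surfaces))
  if (length(miss))
    stop(sprintf("no surface for target propert%s %s",
                 if (length(miss) > 1) "ies" else "y",
                 paste(miss, collapse = ", ")), call. = FALSE)
  nodes <- .surface_nodes(surfaces)
  pass <- sapply(targets, function(t) {
    v <- nodes[[t$property]]
    is.finite(v) & v >= t$lower & v <= t$upper
  })
  pass <- matrix(pass, nrow = nrow(nodes),
                 dimnames = list(NULL, props))
  ok <- rowSums(pass) == length(targets)
  out <- nodes[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- list(
    per_target = colSums(pass), n_nodes = nrow(nodes), pass = pass)
  out
}

#' Select the microMg / nanoMg nodes from the feasible set
#'
#' Among nodes that already reproduce the thermodynamic and structural
#' targets, `micro` is the node whose exchange rate is nearest (on a log
#' scale) to the midpoint of the experimental range, and `nano` the node
#' with the maximal rate.  Ties break toward smaller `eps_io`, then smaller
#' `sigma_io` (second, then first axis).
#'
#' @param nodes Feasible-node data frame from [feasible_set()].
#' @param rate_surface `GridSurface` of exchange rates (1/s) on the same
#'   grid.
#' @param k_exp_range Experimental exchange-rate range, 1/s.
#' @return Object of class `SelectionResult` with `micro` and `nano` node
#'   rows (including the rate) and the full feasible table.
#' @export
select_micro_nano <- function(nodes, rate_surface,
                              k_exp_range = c(5.3e5, 6.7e5)) {
  if (!nrow(nodes)) stop("empty feasible set: nothing to select", call. = FALSE)
  ax <- rate_surface$axes
  i <- match(round(nodes[[names(ax)[1]]], 12), round(ax[[1]], 12))
  j <- match(round(nodes[[names(ax)[2]]], 12), round(ax[[2]], 12))
  if (anyNA(i) || anyNA(j))
    stop("feasible nodes are not on the rate-surface grid", call. = FALSE)
  k <- rate_surface$values[cbind(i, j)]
  if (any(!is.finite(k) | k <= 0))
    stop("rate must be finite and positive at all feasible nodes", call. = FALSE)
  nodes$k <- k
  # tie-break ordering: smaller second axis (eps), then smaller first (sigma)
  ord <- order(nodes[[names(ax)[2]]], nodes[[names(ax)[1]]])
  mid_log <- mean(log(k_exp_range))
  d_micro <- abs(log(k) - mid_log)
  pick <- function(score) {
    cand <- which(score == min(score))
    cand[order(match(cand, ord))[1]]
  }
  i_micro <- pick(d_micro)
  i_nano <- pick(-k)
  structure(list(micro = nodes[i_micro, , drop = FALSE],
                 nano = nodes[i_nano, , drop = FALSE],
                 feasible = nodes, k_exp_range = k_exp_range),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("<SelectionResult>\n micro:\n")
  print(x$micro, row.names = FALSE)
  cat(" nano:\n")
  print(x$nano, row.names = FALSE)
  invisible(x)
}

#' Select combination-rule scaling factors on a lambda grid
#'
#' Among lambda nodes passing every hard target tolerance, returns the node
#' minimizing the weighted squared deviation from the target centers
#' (deviations normalized by each target's tolerance; weights default to
#' equal).  Ties break deterministically toward smaller first-axis lambda
#' (with a warning).  If no node passes, the nearest miss is reported in
#' the error condition rather than silently picking one.
#'
#' @param surfaces Named list of `GridSurface` objects over
#'   `(lambda_sigma, lambda_eps)`.
#' @param targets List of `TargetSpec` objects.
#' @param weights Optional named numeric weights per target property.
#' @return `ScalingFactors` with attributes `node` (the selected row) and
#'   `score`.
#' @export
scan_lambda <- function(surfaces, targets, weights = NULL) {
  feas <- feasible_set(surfaces, targets)
  nodes_all <- .surface_nodes(surfaces)
  score_of <- function(df) {
    s <- 0
    for (t in targets) {
      centre <- t$value %||% mean(c(t$lower, t$upper))
      scale <- t$tolerance %||% ((t$upper - t$lower) / 2)
      if (!is.finite(scale) || scale <= 0) scale <- 1
      w <- (weights[[t$property]] %||% 1)
      s <- s + w * ((df[[t$property]] - centre) / scale)^2
    }
    s
  }
  if (!nrow(feas)) {
    sc <- score_of(nodes_all)
    best <- which.min(sc)
    stop(structure(class = c("mgff_no_feasible_lambda", "error", "condition"),
                   list(message = sprintf(
                     paste0("no lambda node passes all targets; nearest miss at (",
                            "%s = %.4g, %s = %.4g), score %.3g"),
                     names(nodes_all)[1], nodes_all[best, 1],
                     names(nodes_all)[2], nodes_all[best, 2], sc[best]),
                     call = NULL, nearest = nodes_all[best, , drop = FALSE])))
  }
  sc <- score_of(feas)
  cand <- which(abs(sc - min(sc)) <= 1e-12)
  if (length(cand) > 1) {
    warning("tied lambda nodes; breaking toward smaller first-axis lambda",
            call. = FALSE)
    cand <- cand[order(feas[cand, 1], feas[cand, 2])]
  }
  best <- cand[1]
  out <- scaling_factors(feas[best, 1], feas[best, 2],
                         target = attr(surfaces, "target", exact = TRUE) %||% NA_character_)
  attr(out, "node") <- feas[best, , drop = FALSE]
  attr(out, "score") <- sc[best]
  out
}
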