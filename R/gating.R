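# Three-stage gating: morphology (FSC/SSC polygon) -> viability (7-AAD)
# -> IgE/CD117 quadrant analysis.

#' Construct a gate configuration
#'
#' Defines the three-stage gating strategy: a polygonal "cells" gate in
#' FSC/SSC space excluding debris and events smaller than lymphocytes, a
#' 7-AAD viability threshold excluding dead cells, and the FL1/FL2 quadrant
#' thresholds whose double positives (IgE+ CD117+) are counted as mast cells.
#'
#' Boundary convention: events exactly on the polygon boundary are retained,
#' and events exactly at a fluorescence threshold count positive; the
#' viability gate keeps events strictly below `viability_max_fl3`. Thresholds
#' are static per configuration — never derived per sample — so blank-sample
#' statistics (limit of blank) keep their meaning.
#'
#' @param morph_polygon Numeric matrix (>= 3 rows) of `(fsc, ssc)` vertices of
#'   a simple polygon.
#' @param viability_max_fl3 Events with `fl3_7aad` below this are viable.
#' @param ige_threshold FL1 intensity at or above which an event is IgE+.
#' @param cd117_threshold FL2 intensity at or above which an event is CD117+.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(morph_polygon, viability_max_fl3,
                        ige_threshold, cd117_threshold) {
  poly <- as.matrix(morph_polygon)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    stop("morph_polygon must be a matrix of >= 3 (fsc, ssc) vertices",
         call. = FALSE)
  }
  if (anyNA(poly) || any(!is.finite(poly))) {
    stop("morph_polygon vertices must be finite", call. = FALSE)
  }
  if (polygon_self_intersects(poly[, 1], poly[, 2])) {
    stop("morph_polygon must be simple (non-self-intersecting)",
         call. = FALSE)
  }
  if (polygon_area(poly[, 1], poly[, 2]) <= 0) {
    stop("degenerate morph_polygon: zero area", call. = FALSE)
  }
  for (nm in c("viability_max_fl3", "ige_threshold", "cd117_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop(nm, " must be a single positive number", call. = FALSE)
    }
  }
  colnames(poly) <- c("fsc", "ssc")
  structure(list(
    morph_polygon = poly,
    viability_max_fl3 = viability_max_fl3,
    ige_threshold = ige_threshold,
    cd117_threshold = cd117_threshold
  ), class = "gate_config")
}

#' Default gate configuration for the synthetic panel
#'
#' A rectangular "cells" gate starting above debris FSC, a 7-AAD cut-off
#' separating the bright dead population from live cells, and quadrant
#' thresholds well clear of both the autofluorescence background and the
#' bright mast-cell cluster (all in the simulator's linear intensity units).
#'
#' @return A [gate_config()].
#' @export
default_gate_config <- function() {
  gate_config(
    morph_polygon = cbind(fsc = c(100, 2000, 2000, 100),
                          ssc = c(2, 2, 3000, 3000)),
    viability_max_fl3 = 50,
    ige_threshold = 20,
    cd117_threshold = 20
  )
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(px, py) {
  n <- length(px)
  if (n < 4) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      # skip adjacent edges (shared vertex), incl. wrap-around pair (1, n)
      if (i == 1 && j == n) next
      a <- edges[i, ]; b <- edges[j, ]
      if (segments_intersect(c(px[a[1]], py[a[1]]), c(px[a[2]], py[a[2]]),
                             c(px[b[1]], py[b[1]]), c(px[b[2]], py[b[2]]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Vectorised crossing-number point-in-polygon with on-boundary inclusion.
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    # exact on-segment test
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    within <- x >= pmin(x1, x2) & x <= pmax(x1, x2) &
      y >= pmin(y1, y2) & y <= pmax(y1, y2)
    on_edge <- on_edge | (cross == 0 & within)
    # ray-crossing parity
    straddles <- (y1 > y) != (y2 > y)
    if (any(straddles)) {
      xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      flip <- straddles & (x < xint)
      inside <- xor(inside, flip & straddles)
    }
    j <- i
  }
  inside | on_edge
}

#' Apply the morphological "cells" gate
#'
#' Retains exactly the events whose `(fsc, ssc)` lie inside or on the
#' boundary of the gate polygon.
#'
#' @param events An [event_table()].
#' @param gate A [gate_config()].
#' @return The gated [event_table()] subset, order preserved.
#' @export
apply_morphology_gate <- function(events, gate) {
  stopifnot(inherits(gate, "gate_config"))
  keep <- point_in_polygon(events$fsc, events$ssc,
                           gate$morph_polygon[, 1], gate$morph_polygon[, 2])
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the viability gate
#'
#' Retains events whose 7-AAD signal is strictly below
#' `gate$viability_max_fl3` (dye-bright events are dead and excluded).
#'
#' @inheritParams apply_morphology_gate
#' @return The gated [event_table()] subset, order preserved.
#' @export
apply_viability_gate <- function(events, gate) {
  stopifnot(inherits(gate, "gate_config"))
  out <- events[events$fl3_7aad < gate$viability_max_fl3, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate a sample and quantify mast cells as percent double positives
#'
#' Runs the full three-stage strategy: morphology gate, viability gate, then
#' IgE/CD117 quadrant analysis of the viable events. Mast cells are the
#' double-positive (FL1+ FL2+) events; `mast_pct` is their percentage of
#' viable in-gate events. The acquisition-minimum check uses the morphology
#' ("cells") gate count and is reported as a flag, not an error, so
#' statistics remain computable on under-acquired tubes.
#'
#' @param events Raw (ungated) [event_table()].
#' @param gate A [gate_config()].
#' @param min_events Acquisition minimum for the morphology gate.
#' @return A list of class `gating_result` with `n_total`, `n_cells`,
#'   `n_viable`, `quadrant_counts` (FL1-FL2-, FL1+FL2-, FL1-FL2+, FL1+FL2+),
#'   `mast_pct` and `min_events_met`.
#' @export
#' @examples
#' prof <- default_matrix_profile("LN")
#' ev <- simulate_matrix(prof, n_events = 5000, seed = 7)
#' sp <- spike_mast_cells(ev, default_mast_spec(), 5, seed = 8)
#' quantify_mast_cells(sp$events, default_gate_config(), min_events = 1000)
quantify_mast_cells <- function(events, gate, min_events = 0) {
  cells <- apply_morphology_gate(events, gate)
  viable <- apply_viability_gate(cells, gate)
  n_viable <- nrow(viable)
  if (n_viable == 0) {
    stop("no viable in-gate events: mast-cell percentage is undefined",
         call. = FALSE)
  }
  fl1_pos <- viable$fl1_ige >= gate$ige_threshold
  fl2_pos <- viable$fl2_cd117 >= gate$cd117_threshold
  quad <- c(
    nn = sum(!fl1_pos & !fl2_pos),
    pn = sum(fl1_pos & !fl2_pos),
    np = sum(!fl1_pos & fl2_pos),
    pp = sum(fl1_pos & fl2_pos)
  )
  structure(list(
    n_total = nrow(events),
    n_cells = nrow(cells),
    n_viable = n_viable,
    quadrant_counts = quad,
    mast_pct = 100 * quad[["pp"]] / n_viable,
    min_events_met = nrow(cells) >= min_events
  ), class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("<gating_result>\n",
      "  events acquired: ", x$n_total, "\n",
      "  in 'cells' gate: ", x$n_cells,
      if (!x$min_events_met) "  [below acquisition minimum]" else "", "\n",
      "  viable:          ", x$n_viable, "\n",
      "  double positive: ", x$quadrant_counts[["pp"]], "\n",
      "  mast cells:      ", sprintf("%.4f%%", x$mast_pct), "\n", sep = "")
  invisible(x)
}
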