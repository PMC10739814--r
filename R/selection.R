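# Event selection: the three criteria applied to two-hit list-mode data
# before 478 keV imaging.

#' Selection configuration
#'
#' The three selection rules applied to two-hit Si+CdTe events:
#' \enumerate{
#'   \item total energy \eqn{E_1+E_2} inside the prompt-gamma window
#'     (468-488 keV by default, chosen to exclude the 511 keV annihilation
#'     peak); bounds inclusive;
#'   \item scatterer energy \eqn{E_1 < 200} keV (removes backward-scattered
#'     events and noise); strict;
#'   \item events recorded in the deepest scatterer together with the first
#'     absorber are rejected when \eqn{E_1} lies in the Cd fluorescence
#'     X-ray band (inclusive 20-35 keV): such pairs are dominated by
#'     coincidences with CdTe X-rays.
#' }
#'
#' @param window_lo,window_hi Total-energy window bounds (keV).
#' @param e1_max Upper bound on the scatterer energy (keV), strict.
#' @param xray_lo,xray_hi Cd X-ray exclusion band (keV), inclusive.
#' @param apply_xray_rule Apply rule 3 (default `TRUE`).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(window_lo = 468, window_hi = 488,
                             e1_max = 200, xray_lo = 20, xray_hi = 35,
                             apply_xray_rule = TRUE) {
  stopifnot(window_lo < window_hi, xray_lo < xray_hi)
  cfg <- list(window_lo = window_lo, window_hi = window_hi, e1_max = e1_max,
              xray_lo = xray_lo, xray_hi = xray_hi,
              apply_xray_rule = isTRUE(apply_xray_rule))
  class(cfg) <- "selection_config"
  cfg
}

#' Apply the selection criteria to a list-mode set
#'
#' Rules are evaluated with fixed precedence (energy window, then scatterer
#' energy, then X-ray band) so that the per-rule rejection counts are
#' reproducible; the surviving set does not depend on the precedence.  Event
#' order is preserved and the operation is idempotent.
#'
#' @param data A `listmode_set` or event data frame.
#' @param cfg A [selection_config()].
#' @param geometry A [camera_geometry()]; identifies the deepest scatterer
#'   and first absorber layer indices for rule 3.
#' @return A list with `selected` (same type as the input) and `report`
#'   (class `selection_report`: input/output sizes and per-rule rejection
#'   counts).
#' @export
select_events <- function(data, cfg = selection_config(),
                          geometry = camera_geometry()) {
  ev <- as_event_df(data)
  n_in <- nrow(ev)
  etot <- ev$E1_keV + ev$E2_keV
  fail_window <- etot < cfg$window_lo | etot > cfg$window_hi
  fail_e1 <- ev$E1_keV >= cfg$e1_max
  last_scatterer <- geometry$n_scatterers - 1L
  fail_xray <- if (cfg$apply_xray_rule) {
    ev$scatterer_layer == last_scatterer & ev$absorber_layer == 0L &
      ev$E1_keV >= cfg$xray_lo & ev$E1_keV <= cfg$xray_hi
  } else {
    rep(FALSE, n_in)
  }
  # precedence: window, then E1, then X-ray
  rej_window <- sum(fail_window)
  rej_e1 <- sum(!fail_window & fail_e1)
  rej_xray <- sum(!fail_window & !fail_e1 & fail_xray)
  keep <- !fail_window & !fail_e1 & !fail_xray
  out_ev <- ev[keep, , drop = FALSE]
  rownames(out_ev) <- NULL
  report <- structure(
    list(n_in = n_in, n_out = nrow(out_ev),
         rejected_window = rej_window, rejected_e1 = rej_e1,
         rejected_xray = rej_xray, config = cfg),
    class = "selection_report")
  selected <- if (inherits(data, "listmode_set")) {
    out <- data
    out$events <- out_ev
    out
  } else {
    out_ev
  }
  list(selected = selected, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection: %d of %d events kept\n", x$n_out, x$n_in))
  cat(sprintf("  rejected by energy window [%g, %g] keV: %d\n",
              x$config$window_lo, x$config$window_hi, x$rejected_window))
  cat(sprintf("  rejected by E1 >= %g keV: %d\n",
              x$config$e1_max, x$rejected_e1))
  cat(sprintf("  rejected by Cd X-ray band [%g, %g] keV at (last Si, first CdTe): %d\n",
              x$config$xray_lo, x$config$xray_hi, x$rejected_xray))
  invisible(x)
}

#' Write a selection report as key-value text
#'
#' @param report A `selection_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  lines <- c(
    sprintf("n_in: %d", report$n_in),
    sprintf("n_out: %d", report$n_out),
    sprintf("rejected_window: %d", report$rejected_window),
    sprintf("rejected_e1: %d", report$rejected_e1),
    sprintf("rejected_xray: %d", report$rejected_xray))
  writeLines(lines, path)
  invisible(path)
}

#' Boundary-case truth table of the selection rules
#'
#' Enumerates kept/rejected decisions for events straddling the rule
#' boundaries: total energies just inside/outside the inclusive window,
#' scatterer energies at the strict 200 keV cut, and X-ray-band energies at
#' the (last scatterer, first absorber) layer pair.  Serves as a regression
#' fixture for the boundary conventions.
#'
#' @param cfg A [selection_config()].
#' @param geometry A [camera_geometry()].
#' @return Data frame with columns `E1_keV`, `E2_keV`, `E_tot`,
#'   `scatterer_layer`, `absorber_layer`, `kept`, `case`.
#' @export
selection_truth_table <- function(cfg = selection_config(),
                                  geometry = camera_geometry()) {
  last <- geometry$n_scatterers - 1L
  mkrow <- function(e1, etot, s_layer, a_layer, case) {
    data.frame(E1_keV = e1, E2_keV = etot - e1, E_tot = etot,
               scatterer_layer = s_layer, absorber_layer = a_layer,
               case = case)
  }
  eps <- 0.01
  rows <- rbind(
    mkrow(100, cfg$window_lo - eps, 3L, 2L, "below window"),
    mkrow(100, cfg$window_lo, 3L, 2L, "window low edge"),
    mkrow(100, cfg$window_hi, 3L, 2L, "window high edge"),
    mkrow(100, cfg$window_hi + eps, 3L, 2L, "above window"),
    mkrow(cfg$e1_max - eps, 478, 3L, 2L, "E1 just below cut"),
    mkrow(cfg$e1_max, 478, 3L, 2L, "E1 at cut"),
    mkrow(cfg$xray_lo - eps, 478, last, 0L, "below X-ray band at (last,first)"),
    mkrow(cfg$xray_lo, 478, last, 0L, "X-ray band low edge at (last,first)"),
    mkrow(cfg$xray_hi, 478, last, 0L, "X-ray band high edge at (last,first)"),
    mkrow(cfg$xray_hi + eps, 478, last, 0L, "above X-ray band at (last,first)"),
    mkrow(cfg$xray_lo, 478, last - 1L, 0L, "X-ray band energies off (last,first)")
  )
  sel <- select_events(rows, cfg, geometry)$selected
  rows$kept <- rows$case %in% sel$case
  rows
}
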