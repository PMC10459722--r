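#' Bundled hourly derived panel
#'
#' Loads the monitored office day shipped with the package: 8 working hours
#' (9:00-17:00 with a 13:00 lunch break) of hourly IEQ (derived) variables —
#' per-operator PMV, shared desk illuminance, pm2.5 and A-weighted sound
#' level (transcribed fixture file). The PMV column of the requested
#' operator is selected, giving a per-operator raw panel ready for
#' [to_cost_panel()].
#'
#' @param operator Operator number 1-4.
#' @return A raw-oriented [ieq_panel()] with columns `pmv`, `illuminance`,
#'   `pm25`, `sound`.
#' @examples
#' \dontrun{to_cost_panel(ieq_example_panel(1))}
#' @export
ieq_example_panel <- function(operator = 1) {
  stopifnot(operator %in% 1:4)
  path <- system.file("extdata", "hourly_derived_panel.csv",
                      package = "ieqelicit", mustWork = TRUE)
  d <- utils::read.csv(path)
  m <- cbind(pmv = d[[sprintf("pmv_operator%d", operator)]],
             illuminance = d$illuminance, pm25 = d$pm25, sound = d$sound)
  rownames(m) <- as.character(d$hour)
  ieq_panel(m, "raw")
}
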