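#' Load a packaged reference table
#'
#' The package ships, as plain CSV under `inst/extdata/`, the result
#' tables of a simulation campaign over seven patient-specific abdominal
#' aortic aneurysm geometries (cases 2B, 7A, 14B, 16A, 31A, 41B, 63A),
#' five blood rheology models (Cs, CY, HB, N, P) and three inlet
#' velocity profiles (Parabolic, Plug, Womersley). Values are stored
#' exactly as printed (same decimal places) and parsed as decimal
#' numbers, so they round-trip bit-for-bit as decimal strings.
#'
#' Available tables:
#' \describe{
#'   \item{T1}{Per-case inlet radius, mean and peak Reynolds numbers and
#'     Womersley number (`case, inlet_radius_m, mean_re, max_re, alpha`).}
#'   \item{T3}{Grid-convergence study: TAWSS/OSI/RRT on coarse, medium
#'     and fine meshes with reported order and GCI diagnostics.}
#'   \item{T5}{Flow asymmetry and dispersion percentages (`FA_pct`,
#'     `FD_pct`), long format.}
#'   \item{T6}{Thrombus-prone area percentages (`TAWSS_pct`, `OSI_pct`,
#'     `RRT_pct`), long format.}
#'   \item{T7, T8, T9}{Average, maximum and minimum TAWSS/OSI/RRT,
#'     long format.}
#' }
#' Long-format tables have columns `case, rheology, inlet, variable,
#' value` with 105 records per response variable (7 cases x 5 rheologies
#' x 3 inlets).
#'
#' @param table_id One of `"T1"`, `"T3"`, `"T5"`..`"T9"`.
#' @return A `data.frame`; long-format tables additionally carry class
#'   `factorial_table`.
#' @examples
#' t5 <- load_reference_table("T5")
#' subset(t5, case == "2B" & rheology == "Cs" & inlet == "Parabolic")
#' @export
load_reference_table <- function(table_id) {
  valid <- c("T1", "T3", "T5", "T6", "T7", "T8", "T9")
  if (!is.character(table_id) || length(table_id) != 1 ||
      !table_id %in% valid)
    stop("unknown table_id; expected one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  file <- system.file("extdata",
                      paste0("table", sub("T", "", table_id), ".csv"),
                      package = "pulsewss", mustWork = TRUE)
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (table_id %in% c("T5", "T6", "T7", "T8", "T9"))
    class(df) <- c("factorial_table", class(df))
  df
}

#' All fourteen campaign response variables in one long table
#'
#' Binds the long-format reference tables (T5 through T9) into a single
#' `data.frame` holding all fourteen response variables analysed by the
#' robust factorial procedure: `FA_pct`, `FD_pct`, `TAWSS_pct`,
#' `OSI_pct`, `RRT_pct` and the `_ave`/`_max`/`_min` summaries of TAWSS,
#' OSI and RRT.
#'
#' @return A `factorial_table` with 1470 records (14 responses x 105).
#' @export
load_campaign_responses <- function() {
  df <- do.call(rbind, lapply(c("T5", "T6", "T7", "T8", "T9"),
                              load_reference_table))
  rownames(df) <- NULL
  class(df) <- c("factorial_table", "data.frame")
  df
}

#' Names of the fourteen campaign response variables
#' @return Character vector in presentation order.
#' @export
campaign_response_names <- function() {
  c("FA_pct", "FD_pct", "TAWSS_pct", "OSI_pct", "RRT_pct",
    "TAWSS_ave", "OSI_ave", "RRT_ave",
    "TAWSS_max", "OSI_max", "RRT_max",
    "TAWSS_min", "OSI_min", "RRT_min")
}
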