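#' Read a long-format CSV with schema validation
#'
#' Locale-independent (`.` decimal separator, enforced by `read.csv`)
#' reader that fails loudly on missing columns.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return A `data.frame`.
#' @export
read_long_csv <- function(path,
                          required = c("case", "rheology", "inlet",
                                       "variable", "value")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a long-format CSV
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Robust ANOVA p-value matrix for all campaign responses
#'
#' Runs the trimmed-mean two-way ANOVA ([robust_two_way_anova()]) on
#' each of the fourteen packaged response variables and collects the
#' p-values for the rheology main effect (`Rm`), the inlet main effect
#' (`IVD`) and their interaction.
#'
#' @param responses Long table of responses; defaults to the packaged
#'   campaign ([load_campaign_responses()]).
#' @param trim Trim proportion per tail.
#' @return A `data.frame` with columns `variable`, `Rm`, `IVD`,
#'   `interaction`.
#' @export
campaign_anova_matrix <- function(responses = load_campaign_responses(),
                                  trim = 0.2) {
  vars <- intersect(campaign_response_names(),
                    unique(responses$variable))
  rows <- lapply(vars, function(v) {
    fit <- robust_two_way_anova(responses[responses$variable == v, ],
                                trim = trim)
    data.frame(variable = v, Rm = fit$factorA$p.value,
               IVD = fit$factorB$p.value,
               interaction = fit$interaction$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Post hoc contrasts for every campaign response
#'
#' Computes the pooled trimmed-mean pairwise contrasts
#' ([posthoc_contrasts()]) for both factors of each requested response
#' variable, with Hochberg adjustment per (response, factor) family.
#'
#' @inheritParams campaign_anova_matrix
#' @param variables Response variables to analyse (default all present).
#' @return A `data.frame`: `variable`, `factor`, plus the
#'   `contrast_result` columns.
#' @export
campaign_contrasts <- function(responses = load_campaign_responses(),
                               variables = NULL, trim = 0.2) {
  vars <- variables %||% intersect(campaign_response_names(),
                                   unique(responses$variable))
  rows <- lapply(vars, function(v) {
    d <- responses[responses$variable == v, ]
    do.call(rbind, lapply(c("inlet", "rheology"), function(f) {
      cr <- posthoc_contrasts(d, f, trim = trim)
      cbind(variable = v, factor = f, as.data.frame(cr),
            stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the post-solver analysis pipeline
#'
#' Orchestrates the analysis stages on user data or the packaged
#' campaign, writing CSV/JSON outputs plus a machine-readable manifest.
#' Available stages:
#' \describe{
#'   \item{`indices`}{Per-element TAWSS/OSI/RRT maps and summary from a
#'     long WSS CSV (`element,area,t,wss_x,wss_y,wss_z`), given as
#'     `config$wss_csv` (+ `config$period`).}
#'   \item{`flowmetrics`}{Flow asymmetry/dispersion from a plane CSV
#'     (`cell,x,y,z,area,speed`), given as `config$plane_csv`.}
#'   \item{`anova`}{Robust ANOVA matrix and post hoc contrasts from a
#'     long response table (`config$responses_csv`, defaulting to the
#'     packaged campaign).}
#' }
#' Identical config yields identical outputs (all stages are
#' deterministic).
#'
#' @param config Named list: `stages` (character vector, non-empty),
#'   optional input paths as above, `trim`, `band_fraction`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of stage results; side effect: files under
#'   `out_dir` plus `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0)
    stop("`config$stages` must name at least one stage", call. = FALSE)
  bad <- setdiff(stages, c("indices", "flowmetrics", "anova"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trim <- config$trim %||% 0.2
  band <- config$band_fraction %||% 0.15
  results <- list()

  if ("indices" %in% stages) {
    raw <- read_long_csv(config$wss_csv,
                         required = c("element", "area", "t", "wss_x",
                                      "wss_y", "wss_z"))
    raw <- raw[order(raw$element, raw$t), ]
    elems <- unique(raw$element)
    times <- sort(unique(raw$t))
    wss <- array(0, c(length(elems), length(times), 3))
    for (k in 1:3)
      wss[, , k] <- matrix(raw[[c("wss_x", "wss_y", "wss_z")[k]]],
                           length(elems), length(times), byrow = TRUE)
    areas <- raw$area[match(elems, raw$element)]
    field <- surface_wss_field(wss, areas, times,
                               period = config$period %||% 1)
    maps <- wss_indices(field)
    write_long_csv(maps, file.path(out_dir, "index_maps.csv"))
    summ <- summarize_indices(maps)
    jsonlite::write_json(summ[c("tawss", "osi", "rrt", "percentages")],
                         file.path(out_dir, "index_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$indices <- summ
  }

  if ("flowmetrics" %in% stages) {
    cells <- read_long_csv(config$plane_csv,
                           required = c("cell", "x", "y", "z", "area",
                                        "speed"))
    field <- plane_velocity_field(cells)
    fm <- list(flow_asymmetry = flow_asymmetry(field, band),
               flow_dispersion = flow_dispersion(field, band))
    jsonlite::write_json(fm, file.path(out_dir, "flow_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    results$flowmetrics <- fm
  }

  if ("anova" %in% stages) {
    responses <- if (is.null(config$responses_csv))
      load_campaign_responses()
    else read_long_csv(config$responses_csv)
    mat <- campaign_anova_matrix(responses, trim = trim)
    con <- campaign_contrasts(responses, trim = trim)
    write_long_csv(mat, file.path(out_dir, "anova_pvalues.csv"))
    write_long_csv(con, file.path(out_dir, "posthoc_contrasts.csv"))
    results$anova <- list(pvalues = mat, contrasts = con)
  }

  manifest <- list(stages = stages, trim = trim, band_fraction = band,
                   inputs = config[grepl("_csv$", names(config))],
                   package_version =
                     as.character(utils::packageVersion("pulsewss")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
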