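#' Write survey microdata as delimited text
#'
#' One respondent per row, comma-separated, UTF-8, dot decimal. Missing
#' smoking status is written as an empty field. The writer and
#' [read_microdata()] are lossless round-trip partners.
#'
#' @param microdata a `survey_microdata`.
#' @param path output path.
#' @export
write_microdata <- function(microdata, path) {
  cols <- c("area", "cluster", "age_group", "gender", "education",
            "pi", "w_design", "w_post", "smoking")
  stopifnot(all(cols %in% names(microdata)))
  df <- as.data.frame(microdata)[, cols]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read survey microdata from delimited text
#'
#' Validates the documented schema: header columns, positive weights,
#' inclusion probabilities in (0, 1], and known smoking-category labels.
#' Malformed rows are reported with their line number.
#'
#' @param path CSV path.
#' @return a `survey_microdata` data frame; empty smoking fields become
#'   `NA` (item missing).
#' @export
read_microdata <- function(path) {
  cols <- c("area", "cluster", "age_group", "gender", "education",
            "pi", "w_design", "w_post", "smoking")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(area = "character",
                                       smoking = "character"))
  if (!identical(names(df), cols))
    stop("microdata header mismatch: expected ", paste(cols, collapse = ","))
  df$smoking[!is.na(df$smoking) & df$smoking == ""] <- NA_character_
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!is.finite(df$pi) | df$pi <= 0 | df$pi > 1)
  if (length(bad))
    stop("invalid inclusion probability at line ", bad[1] + 1L)
  bad <- which(!is.finite(df$w_design) | df$w_design <= 0 |
                 !is.finite(df$w_post) | df$w_post <= 0)
  if (length(bad)) stop("non-positive weight at line ", line[bad[1]])
  bad <- which(!is.na(df$smoking) & !df$smoking %in% SMOKING_CATEGORIES)
  if (length(bad))
    stop("unknown smoking category '", df$smoking[bad[1]], "' at line ",
         line[bad[1]])
  class(df) <- c("survey_microdata", "data.frame")
  df
}

#' Write/read plain delimited tables (covariates, strata, mortality, direct
#' estimates, summaries)
#'
#' Thin wrappers fixing the package's delimited-text conventions (comma,
#' UTF-8, dot decimal, no quoting, empty field = NA) so that every writer
#' round-trips through its reader.
#'
#' @param df data frame.
#' @param path file path.
#' @return `read_table_csv` returns a data frame with `area` (if present)
#'   read as character.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  hdr <- utils::read.csv(path, nrows = 1)
  cc <- if ("area" %in% names(hdr)) c(area = "character") else NA
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
}

#' Pipeline configuration
#'
#' Assembles and validates the settings of a full pipeline run. Unknown
#' fields are rejected. The configuration can also be read from a YAML file
#' with [read_pipeline_config()].
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_areas,layout synthetic map settings (see
#'   [generate_adjacency()]).
#' @param params generative settings ([gen_params()]).
#' @param design survey design ([survey_design()]).
#' @param covariates area-covariate columns for the smoothing model.
#' @param mcmc list of MCMC settings passed to [bym_spec()]
#'   (`iters`, `burnin`, `thin`, `chains`, `u`, `alpha`, ...).
#' @param ladder named list mapping ladder fit names to the smoking
#'   categories forming each nested indicator, innermost first.
#' @param rr_study RR source for scenario 1.
#' @param rr_mapping stratum mapping preset for scenario 2.
#' @param n_draws Monte-Carlo draws for the PAF/SAM stage.
#' @param outdir output directory (created if needed); `NULL` = no files.
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_areas = 100, layout = "grid",
                            params = gen_params(),
                            design = survey_design(n_insample_areas = 60,
                                                   target_per_area = 50),
                            covariates = c("edu_high", "age65p"),
                            mcmc = list(iters = 2000, burnin = 800,
                                        chains = 2),
                            ladder = list(
                              heavy = "heavy",
                              heavy_moderate = c("heavy", "moderate"),
                              current = c("heavy", "moderate", "light"),
                              ever = c("heavy", "moderate", "light",
                                       "former")),
                            rr_study = "shavelle2008",
                            rr_mapping = "shavelle",
                            n_draws = 1000, outdir = NULL, verbose = TRUE) {
  cfg <- list(seed = seed, n_areas = n_areas, layout = layout,
              params = params, design = design, covariates = covariates,
              mcmc = mcmc, ladder = ladder, rr_study = rr_study,
              rr_mapping = rr_mapping, n_draws = n_draws, outdir = outdir,
              verbose = verbose)
  stopifnot(is.numeric(seed), seed >= 0, n_areas >= 2,
            is.list(ladder), length(ladder) >= 1, n_draws >= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Strict: unknown keys are an error, known keys override the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. `seed`, `outdir`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in intersect(names(raw), c("params", "design", "mcmc")))
    if (nm == "params") raw$params <- do.call(gen_params, raw$params)
    else if (nm == "design") raw$design <- do.call(survey_design, raw$design)
  do.call(pipeline_config, raw)
}

#' Run the full small-area pipeline
#'
#' Simulate -> direct estimation -> BYM2 smoothing (one fit per ladder
#' indicator) -> category decomposition -> PAF/SAM under both scenarios ->
#' reports. Every stage derives its seed from the master seed; identical
#' configurations reproduce identical outputs. If `outdir` is set, all
#' intermediate and final tables are written as delimited text.
#'
#' @param config a `pipeline_config`.
#' @return invisible list with all stage objects: `graph`, `pop`,
#'   `microdata`, `deaths`, `direct` (per ladder fit), `fits`, `comp`,
#'   `comp_strata`, `sam1`, `sam2`, `dic`, `summaries`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  seeds <- split_seed(config$seed, 8)
  t0 <- Sys.time()

  say("[simulate] seed ", config$seed, ": ", config$n_areas, " areas (",
      config$layout, ")")
  graph <- generate_adjacency(config$n_areas, config$layout, seeds[1])
  pop <- generate_population(graph, config$params, seeds[2])
  microdata <- draw_survey(pop, config$design, seeds[3])
  rrset <- load_relative_risks()
  deaths <- generate_mortality(
    pop, rr_point_estimates(rrset, config$rr_study), seed = seeds[4])
  say("[simulate] ", nrow(microdata), " respondents from ",
      length(unique(microdata$area)), " areas, ",
      sprintf("%.1f%%", 100 * mean(is.na(microdata$smoking))),
      " missing smoking status")

  fits <- list(); direct <- list()
  for (i in seq_along(config$ladder)) {
    nm <- names(config$ladder)[i]
    say("[direct/smooth] indicator '", nm, "'")
    direct[[nm]] <- build_direct_table(microdata, config$ladder[[i]])
    # all ladder fits share one seed: common random numbers pair the draws
    # across fits, so differencing cancels Monte-Carlo noise
    spec <- do.call(bym_spec, c(list(covariates = config$covariates,
                                     seed = seeds[5]), config$mcmc))
    fits[[nm]] <- fit_bym(direct[[nm]], pop$areas, graph, spec)
  }
  dic <- lapply(fits, compute_dic)

  say("[decompose] ", length(config$ladder) + 1, " categories")
  comp <- assemble_composition(fits)
  comp_strata <- disaggregate_composition(
    comp, pop, config$params$stratum_offsets)

  say("[sam] scenarios 1 and 2, ", config$n_draws, " draws")
  sam1 <- sam_scenario1(comp_strata, deaths, std = NULL, rrset,
                        study = config$rr_study, n_draws = config$n_draws,
                        seed = seeds[6])
  sam2 <- sam_scenario2(comp_strata, deaths, rrset,
                        mapping = rr_stratum_mapping(config$rr_mapping),
                        n_draws = config$n_draws, seed = seeds[7])

  summaries <- list(prevalence = lapply(fits, prevalence_summaries),
                    composition = composition_summaries(comp),
                    sam1 = sam_report(sam1), sam2 = sam_report(sam2))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$outdir, f)
    write_adjacency(graph, op("adjacency.txt"))
    write_table_csv(pop$areas, op("areas.csv"))
    write_table_csv(pop$strata, op("strata.csv"))
    write_microdata(microdata, op("microdata.csv"))
    write_table_csv(deaths, op("mortality.csv"))
    for (nm in names(direct))
      write_table_csv(direct[[nm]], op(paste0("direct_", nm, ".csv")))
    for (nm in names(fits))
      write_table_csv(summaries$prevalence[[nm]],
                      op(paste0("prevalence_", nm, ".csv")))
    write_table_csv(summaries$composition, op("composition.csv"))
    write_table_csv(summaries$sam1, op("sam_scenario1.csv"))
    write_table_csv(summaries$sam2, op("sam_scenario2.csv"))
    write_table_csv(
      data.frame(model = names(dic),
                 dic = vapply(dic, `[[`, 0, "dic"),
                 p_d = vapply(dic, `[[`, 0, "p_d")),
      op("diagnostics.csv"))
  }
  say(sprintf("[done] %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(graph = graph, pop = pop, microdata = microdata,
                 deaths = deaths, direct = direct, fits = fits,
                 comp = comp, comp_strata = comp_strata,
                 sam1 = sam1, sam2 = sam2, dic = dic,
                 summaries = summaries, config = config))
}
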