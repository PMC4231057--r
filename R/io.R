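#' Tabular schemas used by the pipeline
#'
#' Named list of column-type specifications (`character`, `numeric`,
#' `integer`, `logical`) for the delimited-text tables exchanged between
#' pipeline stages: `permeability`, `teer`, `invivo`, `standards`, `counts`
#' and `grouped`.
#'
#' @return Named list of named character vectors.
#' @export
bbb_schemas <- function() {
  list(
    permeability = c(insert_id = "character", dose_gy = "numeric",
                     day = "numeric", tracer = "character",
                     cell_free = "logical", interval_end_min = "numeric",
                     abluminal_conc = "numeric",
                     luminal_conc_nominal = "numeric"),
    teer = c(insert_id = "character", dose_gy = "numeric", day = "numeric",
             raw_ohm = "numeric"),
    invivo = c(animal_id = "character", age_group = "character",
               region = "character", dose_gy = "numeric",
               timepoint = "character", reading = "numeric",
               tissue_mass_mg = "numeric", extract_volume_ml = "numeric"),
    standards = c(conc_ng_ml = "numeric", reading = "numeric"),
    counts = c(subject_id = "character", dose_gy = "numeric",
               timepoint = "character", assay = "character",
               numerator = "numeric", denominator = "numeric"),
    grouped = c(subject_id = "character", dose_gy = "numeric",
                timepoint = "character", endpoint = "character",
                value = "numeric")
  )
}

coerce_column <- function(x, type, col, path) {
  suppress <- function(expr) suppressWarnings(expr)
  out <- switch(type,
    character = as.character(x),
    numeric = suppress(as.numeric(x)),
    integer = suppress(as.integer(x)),
    logical = suppress(as.logical(x)),
    stop("unknown schema type: ", type))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad))
    stop("unparseable ", type, " value '", x[bad[1]], "' in column '", col,
         "', row ", bad[1], " of ", path)
  out
}

#' Load and validate a delimited table against a schema
#'
#' Reads a comma-separated UTF-8 file with header, checks that every
#' required column is present, coerces columns to their schema types
#' (erroring with the row number on unparseable values) and preserves any
#' unknown columns.
#'
#' @param path Path to a CSV file.
#' @param schema_name One of the names of [bbb_schemas()].
#' @return The validated data frame.
#' @export
load_table <- function(path, schema_name) {
  schemas <- bbb_schemas()
  if (!schema_name %in% names(schemas))
    stop("unknown schema '", schema_name, "'; available: ",
         paste(names(schemas), collapse = ", "))
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- schemas[[schema_name]]
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop("table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in names(schema))
    raw[[col]] <- coerce_column(raw[[col]], schema[[col]], col, path)
  message("loaded ", nrow(raw), " row(s) from ", path,
          " (schema '", schema_name, "')")
  raw
}

#' Load a pipeline run configuration
#'
#' Reads a YAML key-value file (or passes a list through) and fills in
#' defaults: assay geometry, blank TEER, statistics options, bootstrap
#' resamples. A `seed` is required for any simulation stage.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A named list of configuration values.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = NULL,
    output_dir = "bbbflux_out",
    luminal_volume = 70,
    abluminal_volume = 530,
    insert_area = 0.33,
    sample_times = c(20, 40, 60),
    donor_concentration = c(fluorescein = 10, eb_albumin = 165),
    blank_teer = 70,
    extract_volume_ml = 0.5,
    n_inserts = 3,
    n_cell_free = 3,
    noise_cv = 0.1,
    bootstrap_resamples = 2000,
    bonferroni_family = "dose_by_time"
  )
  utils::modifyList(defaults, config)
}

write_stage <- function(tables, out_dir, stage, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  prov <- list(stage = stage, seed = config$seed,
               package_version = as.character(utils::packageVersion("bbbflux")),
               parameters = config[setdiff(names(config), "output_dir")],
               tables = names(tables))
  yaml::write_yaml(prov, file.path(out_dir,
                                   paste0("provenance_", stage, ".yaml")))
  invisible(names(tables))
}

require_input <- function(out_dir, name, stage) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  if (!file.exists(path))
    stop("dependency error: stage '", stage, "' needs ", path,
         "; run the upstream stage first")
  path
}

#' Run a pipeline stage
#'
#' Executes one stage of the assay-analysis pipeline against an output
#' directory of CSV tables. `"simulate"` generates the full synthetic study
#' from the default (or overridden) kinetics and effect structure;
#' `"permeability"` fits Pe and TEER; `"evansblue"` fits the standard curve,
#' quantifies tissue content and computes fold-changes vs sham; `"assays"`
#' summarizes the count endpoints; `"stats"` runs dose-by-timepoint ANOVA
#' with Bonferroni post-tests per endpoint; `"report"` renders group
#' means +/- SD with star codes. Each stage writes its result tables plus a
#' provenance block (seed, parameters, package version).
#'
#' @param config A configuration list or YAML path (see [load_config()]).
#' @param subcommand One of `"simulate"`, `"permeability"`, `"evansblue"`,
#'   `"assays"`, `"stats"`, `"report"`.
#' @return Invisibly, the paths of the tables written by the stage.
#' @examples
#' \donttest{
#' cfg <- list(seed = 1, output_dir = tempfile("bbb"))
#' run_pipeline(cfg, "simulate")
#' run_pipeline(cfg, "permeability")
#' }
#' @export
run_pipeline <- function(config, subcommand) {
  valid <- c("simulate", "permeability", "evansblue", "assays", "stats",
             "report")
  if (!is.character(subcommand) || length(subcommand) != 1 ||
      !subcommand %in% valid)
    stop("usage: run_pipeline(config, subcommand) with subcommand one of: ",
         paste(valid, collapse = ", "))
  config <- load_config(config)
  out_dir <- config$output_dir

  if (subcommand == "simulate") {
    if (is.null(config$seed))
      stop("`seed` is required in the config for simulation")
    kin <- if (!is.null(config$kinetics)) config$kinetics else
      default_kinetics()
    eff <- if (!is.null(config$effects)) config$effects else default_effects()
    perm <- simulate_permeability_dataset(
      kin, n_inserts = config$n_inserts, n_cell_free = config$n_cell_free,
      noise_cv = config$noise_cv, seed = config$seed)
    vivo <- simulate_in_vivo_dataset(eff, seed = config$seed + 1L)
    counts <- simulate_count_assays(eff, seed = config$seed + 2L)
    return(invisible(write_stage(
      list(permeability = perm$permeability, teer = perm$teer,
           invivo = vivo$invivo, standards = vivo$standards, counts = counts),
      out_dir, "simulate", config)))
  }

  if (subcommand == "permeability") {
    perm <- load_table(require_input(out_dir, "permeability", subcommand),
                       "permeability")
    teer <- load_table(require_input(out_dir, "teer", subcommand), "teer")
    fit <- fit_permeability(perm, abluminal_volume = config$abluminal_volume,
                            insert_area = config$insert_area)
    teer_res <- cbind(teer[c("insert_id", "dose_gy", "day")],
                      compute_teer(teer$raw_ohm, area = config$insert_area,
                                   blank = config$blank_teer))
    return(invisible(write_stage(
      list(permeability_results = fit$results, teer_results = teer_res),
      out_dir, "permeability", config)))
  }

  if (subcommand == "evansblue") {
    vivo <- load_table(require_input(out_dir, "invivo", subcommand), "invivo")
    std <- load_table(require_input(out_dir, "standards", subcommand),
                      "standards")
    curve <- fit_standard_curve(std)
    vivo$value <- as.numeric(quantify_tissue(
      vivo$reading, vivo$tissue_mass_mg, curve,
      extract_volume = vivo$extract_volume_ml))
    folds <- fold_change_vs_sham(
      vivo, value = "value", n_boot = config$bootstrap_resamples,
      seed = if (is.null(config$seed)) 1L else config$seed)
    return(invisible(write_stage(
      list(invivo_results = vivo, invivo_foldchange = folds),
      out_dir, "evansblue", config)))
  }

  if (subcommand == "assays") {
    counts <- load_table(require_input(out_dir, "counts", subcommand),
                         "counts")
    counts$value <- NA_real_
    is_cep <- counts$assay == "cep"
    is_sen <- counts$assay == "senescence"
    is_den <- counts$assay == "cell_density"
    counts$value[is_cep] <- cep_rate(counts$numerator[is_cep],
                                     counts$denominator[is_cep])
    counts$value[is_sen] <- senescence_fraction(
      counts$numerator[is_sen], counts$denominator[is_sen])$percent
    counts$value[is_den] <- cell_density(counts$numerator[is_den],
                                         counts$denominator[is_den])
    return(invisible(write_stage(list(assay_results = counts), out_dir,
                                 "assays", config)))
  }

  grouped_endpoints <- function() {
    tabs <- list()
    p <- file.path(out_dir, "permeability_results.csv")
    if (file.exists(p)) {
      pr <- utils::read.csv(p, stringsAsFactors = FALSE)
      pr <- pr[!pr$excluded, ]
      for (tr in unique(pr$tracer))
        tabs[[paste0("pe_", tr)]] <- data.frame(
          subject_id = pr$insert_id[pr$tracer == tr],
          dose_gy = pr$dose_gy[pr$tracer == tr],
          timepoint = as.character(pr$day[pr$tracer == tr]),
          value = pr$pe[pr$tracer == tr])
    }
    p <- file.path(out_dir, "teer_results.csv")
    if (file.exists(p)) {
      tr <- utils::read.csv(p, stringsAsFactors = FALSE)
      tabs$teer <- data.frame(subject_id = tr$insert_id, dose_gy = tr$dose_gy,
                              timepoint = as.character(tr$day),
                              value = tr$teer)
    }
    p <- file.path(out_dir, "invivo_results.csv")
    if (file.exists(p)) {
      iv <- utils::read.csv(p, stringsAsFactors = FALSE)
      for (key in split(iv, interaction(iv$age_group, iv$region)))
        if (nrow(key))
          tabs[[paste0("evans_blue_", key$age_group[1], "_",
                       key$region[1])]] <- data.frame(
            subject_id = key$animal_id, dose_gy = key$dose_gy,
            timepoint = key$timepoint, value = key$value)
    }
    p <- file.path(out_dir, "assay_results.csv")
    if (file.exists(p)) {
      cn <- utils::read.csv(p, stringsAsFactors = FALSE)
      for (a in unique(cn$assay))
        tabs[[a]] <- data.frame(subject_id = cn$subject_id[cn$assay == a],
                                dose_gy = cn$dose_gy[cn$assay == a],
                                timepoint = cn$timepoint[cn$assay == a],
                                value = cn$value[cn$assay == a])
    }
    if (!length(tabs))
      stop("dependency error: stage '", subcommand, "' found no upstream ",
           "result tables in ", out_dir)
    tabs
  }

  if (subcommand == "stats") {
    tabs <- grouped_endpoints()
    out <- list()
    for (nm in names(tabs)) {
      tab <- tabs[[nm]]
      if (length(unique(tab$timepoint)) >= 2) {
        an <- two_way_anova(tab, response = "value",
                            factors = c("dose_gy", "timepoint"))
        cmp <- bonferroni_vs_sham(an, family = config$bonferroni_family)
        out[[paste0("stats_anova_", nm)]] <- an$anova_table
        out[[paste0("stats_posttests_", nm)]] <- cmp
      } else {
        an <- one_way_anova(tab, response = "value", group = "dose_gy")
        out[[paste0("stats_anova_", nm)]] <- an$anova_table
        out[[paste0("stats_posttests_", nm)]] <- an$comparisons
      }
    }
    return(invisible(write_stage(out, out_dir, "stats", config)))
  }

  if (subcommand == "report") {
    tabs <- grouped_endpoints()
    out <- list()
    for (nm in names(tabs)) {
      tab <- tabs[[nm]]
      agg <- stats::aggregate(value ~ dose_gy + timepoint, data = tab,
                              FUN = function(v) c(mean = mean(v),
                                                  sd = stats::sd(v),
                                                  n = length(v)))
      rep_tab <- data.frame(agg[c("dose_gy", "timepoint")],
                            mean = agg$value[, "mean"],
                            sd = agg$value[, "sd"], n = agg$value[, "n"])
      post_path <- file.path(out_dir, paste0("stats_posttests_", nm, ".csv"))
      if (file.exists(post_path)) {
        post <- utils::read.csv(post_path, stringsAsFactors = FALSE)
        idx <- match(paste(rep_tab$dose_gy, rep_tab$timepoint),
                     paste(post$dose, post$timepoint))
        rep_tab$stars <- ifelse(is.na(idx), "", post$stars[idx])
      }
      out[[paste0("report_", nm)]] <- rep_tab
    }
    return(invisible(write_stage(out, out_dir, "report", config)))
  }
}
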