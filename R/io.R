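# File I/O and pipeline assembly.
#
# All tables are plain CSV with a required header; lines starting with '#'
# are metadata comments (tool version, seed, input checksums) and are
# skipped on read. RBA values are percentages in files (column suffix
# `_percent`) and fractions everywhere in memory.

FOODS_COLUMNS <- c("food", "roast_day", "replicate", "concentration_mg_per_kg")
ASSAY_COLUMNS <- c("assay_id", "food", "roast_day", "c_iv_mg_per_L",
                   "c_av_mg_per_L", "v_iv_L", "t_s_mg_per_kg", "m_s_kg",
                   "dilution_ratio", "teer_ok")
SURVEY_COLUMNS <- c("person_id", "group", "food", "intake_kg_per_day")

meta_header <- function(seed = NULL, inputs = NULL) {
  v <- as.character(utils::packageVersion("fluorisk"))
  parts <- c(sprintf("# fluorisk %s", v),
             if (!is.null(seed)) sprintf("seed=%d", as.integer(seed)),
             if (length(inputs)) {
               sums <- tools::md5sum(inputs)
               sprintf("inputs=%s",
                       paste(sprintf("%s:%s", basename(inputs), unname(sums)),
                             collapse = ","))
             })
  paste(parts, collapse = "; ")
}

write_csv_with_meta <- function(df, path, seed = NULL, inputs = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(seed, inputs), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required, numeric_cols, unique_key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(basename(path), ": no data rows", call. = FALSE)
    return(df)
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data row(s) %s",
                   basename(path), col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("%s: missing value in column '%s' at data row(s) %s",
                   basename(path), col,
                   paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!is.null(unique_key)) {
    key <- do.call(paste, c(df[unique_key], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("%s: duplicate %s key at data row(s) %s", basename(path),
                   paste(unique_key, collapse = "/"),
                   paste(dup, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read a food concentration table
#'
#' @param path CSV with columns `food`, `roast_day`, `replicate`,
#'   `concentration_mg_per_kg`.
#' @return Data frame with in-memory column names (`concentration`, mg/kg);
#'   duplicate `(food, roast_day, replicate)` keys are rejected with their
#'   row numbers.
#' @export
read_foods_csv <- function(path) {
  df <- read_csv_checked(path, FOODS_COLUMNS,
                         c("roast_day", "replicate", "concentration_mg_per_kg"),
                         unique_key = c("food", "roast_day", "replicate"))
  if (nrow(df) && any(df$concentration_mg_per_kg < 0)) {
    stop("negative concentrations in ", basename(path), call. = FALSE)
  }
  names(df)[names(df) == "concentration_mg_per_kg"] <- "concentration"
  df
}

#' Write a food concentration table
#'
#' @param df data frame with columns `food`, `roast_day`, `replicate`,
#'   `concentration`.
#' @param path output CSV path.
#' @param seed seed recorded in the metadata header.
#' @export
write_foods_csv <- function(df, path, seed = NULL) {
  out <- data.frame(food = df$food, roast_day = df$roast_day,
                    replicate = df$replicate,
                    concentration_mg_per_kg = df$concentration)
  write_csv_with_meta(out, path, seed = seed)
}

#' Read a transport assay table
#'
#' @param path CSV with the `assays.csv` schema (concentrations in mg/L,
#'   volume in L, sample total in mg/kg, mass in kg, `teer_ok` boolean).
#' @return Data frame with in-memory field names (`c_iv`, `c_av`, `v_iv`,
#'   `t_s`, `m_s`, ...).
#' @export
read_assays_csv <- function(path) {
  df <- read_csv_checked(path, ASSAY_COLUMNS,
                         c("roast_day", "c_iv_mg_per_L", "c_av_mg_per_L",
                           "v_iv_L", "t_s_mg_per_kg", "m_s_kg"),
                         unique_key = "assay_id")
  ren <- c(c_iv_mg_per_L = "c_iv", c_av_mg_per_L = "c_av", v_iv_L = "v_iv",
           t_s_mg_per_kg = "t_s", m_s_kg = "m_s")
  names(df)[match(names(ren), names(df))] <- ren
  if (nrow(df)) df$teer_ok <- as.logical(df$teer_ok)
  df
}

#' Write a transport assay table
#'
#' @param df data frame with in-memory assay fields.
#' @param path output CSV path.
#' @param seed seed recorded in the metadata header.
#' @export
write_assays_csv <- function(df, path, seed = NULL) {
  out <- data.frame(assay_id = df$assay_id, food = df$food,
                    roast_day = df$roast_day, c_iv_mg_per_L = df$c_iv,
                    c_av_mg_per_L = df$c_av, v_iv_L = df$v_iv,
                    t_s_mg_per_kg = df$t_s, m_s_kg = df$m_s,
                    dilution_ratio = df$dilution_ratio, teer_ok = df$teer_ok)
  write_csv_with_meta(out, path, seed = seed)
}

#' Read an intake survey table
#'
#' @param path CSV with columns `person_id`, `group`, `food`,
#'   `intake_kg_per_day`.
#' @return Data frame.
#' @export
read_intake_survey_csv <- function(path) {
  read_csv_checked(path, SURVEY_COLUMNS, c("intake_kg_per_day"))
}

#' Write an intake survey table
#'
#' @param df survey data frame.
#' @param path output CSV path.
#' @param seed seed recorded in the metadata header.
#' @export
write_intake_survey_csv <- function(df, path, seed = NULL) {
  write_csv_with_meta(df[SURVEY_COLUMNS], path, seed = seed)
}

#' Read a population exposure-constants config
#'
#' @param path YAML file shaped like [default_population_config()].
#' @return Nested config list.
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (g in names(cfg)) {
    for (f in c("bw", "at", "ef", "ed", "rfd")) {
      check_positive(cfg[[g]][[f]], paste0(g, "$", f))
    }
    cfg[[g]]$ir <- lapply(cfg[[g]]$ir, function(v) unlist(v))
  }
  cfg
}

#' Write a population exposure-constants config
#'
#' @param config nested list shaped like [default_population_config()].
#' @param path output YAML path.
#' @export
write_population_config <- function(config, path) {
  out <- lapply(config, function(g) {
    g$ir <- lapply(g$ir, as.list)
    g
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full risk-assessment pipeline
#'
#' Orchestrates the stages in study order: bioavailability summary (if
#' assays are supplied), deterministic point risk per food, stage and group,
#' maximum-intake inversion (with the RBA-corrected variant when
#' bioavailability is available), intake distribution fitting (if a survey
#' is supplied) and Monte Carlo risk simulation. Stages whose inputs are
#' absent are skipped with a message. Output CSVs carry a metadata header
#' with tool version, seed and input checksums; partial outputs are removed
#' if a stage fails.
#'
#' @param foods path to `foods.csv` (required).
#' @param assays optional path to `assays.csv`.
#' @param survey optional path to `intake_survey.csv`.
#' @param populations optional path to a populations YAML (defaults to the
#'   built-in study constants).
#' @param out_dir output directory for the result CSVs.
#' @param seed master seed for the Monte Carlo stage (required when a survey
#'   is supplied).
#' @param n_iter Monte Carlo iterations.
#' @param truncate_negative clamp negative Monte Carlo draws at zero?
#' @return Invisibly, the report bundle: a list with elements
#'   `bioavailability`, `risk_point`, `irmax`, `fits`, `mc_risk` (data
#'   frames or `NULL` for skipped stages) and `meta`.
#' @export
run_pipeline <- function(foods, assays = NULL, survey = NULL,
                         populations = NULL, out_dir = ".", seed = NULL,
                         n_iter = 10000, truncate_negative = FALSE) {
  inputs <- c(foods, assays, survey)
  conc <- read_foods_csv(foods)
  if (nrow(conc) == 0L) stop("foods table is empty", call. = FALSE)
  cfg <- if (is.null(populations)) {
    default_population_config()
  } else {
    read_population_config(populations)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on.exit(unlink(written), add = TRUE)  # cleared on success below
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_csv_with_meta(df, p, seed = seed, inputs = inputs)
    written <<- c(written, p)
    p
  }

  # stage means over replicates
  agg <- stats::aggregate(concentration ~ food + roast_day, conc, mean)

  ## bioavailability ----
  bio <- NULL
  if (!is.null(assays)) {
    adf <- read_assays_csv(assays)
    bio <- summarize_bioavailability(adf, conc)
    emit(data.frame(food = bio$food, roast_day = bio$roast_day,
                    rba_percent = 100 * bio$rba,
                    absorbed_mg_per_kg = bio$absorbed_mg_per_kg,
                    n_assays = bio$n_assays),
         "bioavailability.csv")
  } else {
    message("no assays supplied: bioavailability stage skipped")
  }

  ## deterministic point risk ----
  grid <- expand.grid(i = seq_len(nrow(agg)), group = names(cfg),
                      stringsAsFactors = FALSE)
  risk_point <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    row <- agg[grid$i[r], ]
    if (!row$food %in% names(cfg[[grid$group[r]]]$ir)) return(NULL)
    p <- population_parameters(grid$group[r], row$food, config = cfg)
    add <- average_daily_dose(row$concentration, p)
    hq <- hazard_quotient(add, p$rfd)
    data.frame(food = row$food, roast_day = row$roast_day,
               group = grid$group[r], c_mg_per_kg = row$concentration,
               add = add, hq = as.numeric(hq),
               at_risk = attr(hq, "at_risk"))
  }))
  risk_point <- risk_point[order(risk_point$group, risk_point$food,
                                 risk_point$roast_day), , drop = FALSE]
  rownames(risk_point) <- NULL
  emit(risk_point, "risk_point.csv")

  ## maximum allowable intake ----
  irmax_tab <- do.call(rbind, lapply(seq_len(nrow(risk_point)), function(r) {
    row <- risk_point[r, ]
    p <- population_parameters(row$group, row$food, config = cfg)
    rba <- if (!is.null(bio)) {
      hit <- bio$rba[bio$food == row$food & bio$roast_day == row$roast_day]
      if (length(hit) == 1L && hit > 0) hit else NA_real_
    } else NA_real_
    data.frame(food = row$food, roast_day = row$roast_day, group = row$group,
               ir_max_kg_per_day = ir_max(row$c_mg_per_kg, p),
               ir_max_rba_kg_per_day =
                 if (is.na(rba)) NA_real_ else ir_max(row$c_mg_per_kg, p, rba = rba),
               rba_percent_used = if (is.na(rba)) NA_real_ else 100 * rba)
  }))
  rownames(irmax_tab) <- NULL
  emit(irmax_tab, "irmax.csv")

  ## intake distribution fitting + Monte Carlo ----
  fits_tab <- NULL; mc_tab <- NULL
  if (!is.null(survey)) {
    if (is.null(seed)) {
      stop("a 'seed' is required when running the Monte Carlo stage",
           call. = FALSE)
    }
    sdf <- read_intake_survey_csv(survey)
    sim_cfg <- simulation_config(seed = seed, n_iter = n_iter,
                                 truncate_negative = truncate_negative)
    fits <- list()
    fit_rows <- list()
    for (g in unique(sdf$group)) {
      for (f in unique(sdf$food[sdf$group == g])) {
        x <- sdf$intake_kg_per_day[sdf$group == g & sdf$food == f]
        rk <- select_distribution(x)
        fits[[paste(g, f)]] <- rk[[1L]]
        tab <- as.data.frame(rk)
        fit_rows[[paste(g, f)]] <- cbind(group = g, food = f, tab)
      }
    }
    fits_tab <- do.call(rbind, fit_rows)
    rownames(fits_tab) <- NULL
    emit(fits_tab, "fits.csv")

    mc_rows <- list()
    for (g in intersect(unique(sdf$group), names(cfg))) {
      for (day in sort(unique(agg$roast_day))) {
        scen <- list()
        for (f in intersect(unique(agg$food), names(cfg[[g]]$ir))) {
          if (!paste(g, f) %in% names(fits)) next
          reps <- conc$concentration[conc$food == f & conc$roast_day == day]
          if (length(reps) < 2L) next
          c_dist <- fit_mle(reps, "normal")
          scen[[f]] <- scenario_spec(
            f, day, g, c_dist, fits[[paste(g, f)]],
            population_parameters(g, f, config = cfg))
        }
        if (length(scen) == 0L) next
        summaries <- c(lapply(scen, simulate_hq, config = sim_cfg),
                       list(ALL = simulate_hi(scen, sim_cfg)))
        mc_rows <- c(mc_rows, lapply(summaries, function(s) {
          data.frame(food = s$food, roast_day = s$roast_day, group = s$group,
                     mean = s$mean, p05 = s$p05, p95 = s$p95,
                     prob_hq_gt_1 = s$prob_hq_above_1, n_iter = s$n_iter,
                     seed = s$seed)
        }))
      }
    }
    mc_tab <- do.call(rbind, mc_rows)
    rownames(mc_tab) <- NULL
    emit(mc_tab, "mc_risk.csv")
  } else {
    message("no survey supplied: distribution fitting and Monte Carlo skipped")
  }

  on.exit()  # success: keep outputs
  invisible(list(bioavailability = bio, risk_point = risk_point,
                 irmax = irmax_tab, fits = fits_tab, mc_risk = mc_tab,
                 meta = list(seed = seed, n_iter = n_iter,
                             inputs = inputs, out_dir = out_dir)))
}
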