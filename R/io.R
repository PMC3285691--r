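# Numeric payload columns are serialized at full precision with "%.17g" and
# parsed back with as.numeric (correctly rounding), so write/load round trips
# are bit-exact.
NUM_COLS <- c("value", "count")
INT_COLS <- c("age", "year")

read_table_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default =
                                                  readr::col_character()))
  for (nm in intersect(NUM_COLS, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in intersect(INT_COLS, names(df))) df[[nm]] <- as.integer(df[[nm]])
  df
}

write_table_csv <- function(df, path) {
  for (nm in intersect(NUM_COLS, names(df))) {
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  readr::write_csv(df, path, progress = FALSE)
}

ast_to_df <- function(m) {
  tibble::tibble(age = rep(as.integer(rownames(m)), 2),
                 sex = rep(SEXES, each = nrow(m)),
                 value = as.vector(m))
}

df_to_ast <- function(df, age_max, table) {
  m <- blank_ast(age_max, NA_real_)
  m[cbind(df$age + 1L, match(df$sex, SEXES))] <- df$value
  if (anyNA(m)) {
    i <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("table '%s' is missing the cell age %d, sex %s", table,
                 i[1] - 1L, SEXES[i[2]]), call. = FALSE)
  }
  m
}

#' Write an input bundle to a directory of tabular files
#'
#' The on-disk format is a set of long-format CSV tables (columns such as
#' `age`, `sex`, `class`, `disease`, `value`) plus a JSON manifest recording
#' the bundle dimensions and the file names. CSVs use shortest round-trip
#' number formatting, so [load_bundle()] restores values bit-exactly.
#'
#' @param bundle A [smoking_bundle()].
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "smoking_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) write_table_csv(df, file.path(path, file))
  w(ast_to_df(bundle$demography$population), "population.csv")
  nb <- bundle$demography$newborns
  w(tibble::tibble(year = rep(seq_len(nrow(nb)), 2),
                   sex = rep(SEXES, each = nrow(nb)),
                   value = as.vector(nb)), "newborns.csv")
  cls <- smoking_classes(bundle$k_classes)
  ages <- ages_of(bundle$age_max)
  w(tibble::tibble(
    age = rep(ages, times = 2 * length(cls)),
    sex = rep(rep(SEXES, each = length(ages)), length(cls)),
    class = rep(cls, each = 2 * length(ages)),
    value = as.vector(bundle$smoking)), "smoking.csv")
  w(do.call(rbind, lapply(c("start", "quit", "restart"), function(nm) {
    cbind(rate = nm, ast_to_df(bundle$rates[[nm]]))
  })), "transitions.csv")
  w(do.call(rbind, lapply(bundle$diseases, function(d) {
    do.call(rbind, lapply(
      c("incidence", "prevalence", "excess_mortality"), function(ms) {
        cbind(disease = d$name, measure = ms, ast_to_df(d[[ms]]))
      }))
  })), "diseases.csv")
  rr_df <- function(rr_current, rr_former, label) {
    tibble::tibble(
      disease = label,
      class = rep(cls[-1], each = length(ages)),
      age = rep(ages, length(cls) - 1L),
      value = c(rr_current, as.vector(rr_former)))
  }
  w(do.call(rbind, lapply(bundle$diseases, function(d) {
    rr_df(d$rr_current, d$rr_former, d$name)
  })), "disease_rr.csv")
  w(ast_to_df(bundle$mortality$m_total), "mortality.csv")
  mrr <- rr_df(bundle$mortality$rr_current, bundle$mortality$rr_former,
               "all_cause")
  w(mrr[, c("class", "age", "value")], "mortality_rr.csv")
  jsonlite::write_json(
    list(format = "smokesim-bundle",
         package_version = as.character(packageVersion("smokesim")),
         age_max = bundle$age_max, k_classes = bundle$k_classes,
         baseline_year = bundle$baseline_year,
         diseases = unname(vapply(bundle$diseases, `[[`, "", "name")),
         files = c("population.csv", "newborns.csv", "smoking.csv",
                   "transitions.csv", "diseases.csv", "disease_rr.csv",
                   "mortality.csv", "mortality_rr.csv")),
    file.path(path, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load an input bundle from a directory
#'
#' Reads a directory written by [write_bundle()] (or assembled by hand in the
#' same format), reconstructs every table, and validates all bundle
#' invariants; any missing table, missing `(age, sex)` cell, or out-of-range
#' value raises an error naming the offending table and cell.
#'
#' @param path Directory containing `manifest.json` and the CSV tables.
#' @return A validated [smoking_bundle()].
#' @export
load_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("missing table: manifest.json in ", path,
                                  call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (f in mf$files) {
    if (!file.exists(file.path(path, f))) {
      stop("missing table: ", f, call. = FALSE)
    }
  }
  am <- as.integer(mf$age_max)
  k <- as.integer(mf$k_classes)
  ages <- ages_of(am)
  cls <- smoking_classes(k)
  rd <- function(f) read_table_csv(file.path(path, f))

  population <- df_to_ast(rd("population.csv"), am, "population")
  nb_df <- rd("newborns.csv")
  n_years <- max(nb_df$year)
  newborns <- matrix(NA_real_, n_years, 2, dimnames = list(NULL, SEXES))
  newborns[cbind(nb_df$year, match(nb_df$sex, SEXES))] <- nb_df$value
  if (anyNA(newborns)) stop("table 'newborns' has missing cells",
                            call. = FALSE)

  sm_df <- rd("smoking.csv")
  smoking <- array(NA_real_, dim = c(am + 1L, 2L, length(cls)),
                   dimnames = list(age = ages, sex = SEXES, class = cls))
  smoking[cbind(sm_df$age + 1L, match(sm_df$sex, SEXES),
                match(sm_df$class, cls))] <- sm_df$value
  if (anyNA(smoking)) {
    i <- which(is.na(smoking), arr.ind = TRUE)[1, ]
    stop(sprintf("table 'smoking' is missing age %d, sex %s, class %s",
                 i[1] - 1L, SEXES[i[2]], cls[i[3]]), call. = FALSE)
  }

  tr_df <- rd("transitions.csv")
  rates <- lapply(setNames(nm = c("start", "quit", "restart")), function(nm) {
    df_to_ast(tr_df[tr_df$rate == nm, ], am, paste0("transitions/", nm))
  })

  dis_df <- rd("diseases.csv")
  rr_df <- rd("disease_rr.csv")
  parse_rr <- function(df, table) {
    rc <- df[df$class == "current", ]
    rr_current <- rep(NA_real_, am + 1L)
    rr_current[rc$age + 1L] <- rc$value
    rr_former <- matrix(NA_real_, am + 1L, k)
    fm <- df[startsWith(df$class, "former_"), ]
    kk <- as.integer(sub("former_", "", fm$class)) + 1L
    rr_former[cbind(fm$age + 1L, kk)] <- fm$value
    if (anyNA(rr_current) || anyNA(rr_former)) {
      stop("table '", table, "' has missing relative-risk cells",
           call. = FALSE)
    }
    list(current = rr_current, former = rr_former)
  }
  diseases <- lapply(setNames(nm = mf$diseases), function(dn) {
    dd <- dis_df[dis_df$disease == dn, ]
    if (nrow(dd) == 0) stop("missing table rows for disease ", dn,
                            call. = FALSE)
    grab <- function(ms) df_to_ast(dd[dd$measure == ms, ], am,
                                   paste0(dn, "/", ms))
    rr <- parse_rr(rr_df[rr_df$disease == dn, ], paste0(dn, "/rr"))
    disease_definition(dn, grab("incidence"), grab("prevalence"),
                       grab("excess_mortality"), rr$current, rr$former)
  })

  m_total <- df_to_ast(rd("mortality.csv"), am, "mortality")
  mrr <- parse_rr(rd("mortality_rr.csv"), "mortality_rr")

  smoking_bundle(
    demography = list(population = population, newborns = newborns),
    smoking = smoking, rates = rates, diseases = diseases,
    mortality = list(m_total = m_total, rr_current = mrr$current,
                     rr_former = mrr$former),
    age_max = am, k_classes = k,
    baseline_year = as.integer(mf$baseline_year), validate = TRUE
  )
}

# ---- projection results -----------------------------------------------------

state_df <- function(result, i) {
  cnt <- result$counts[[i]]
  dn <- dimnames(cnt)
  tibble::tibble(
    year = result$years[i],
    age = rep(as.integer(dn$age), times = 2 * length(dn$class)),
    sex = rep(rep(dn$sex, each = length(dn$age)), length(dn$class)),
    class = rep(dn$class, each = 2 * length(dn$age)),
    count = as.vector(cnt))
}

prev_df <- function(result, i) {
  pv <- result$prev[[i]]
  dn <- dimnames(pv)
  n_asc <- prod(dim(pv)[1:3])
  tibble::tibble(
    year = result$years[i],
    disease = rep(dn$disease, each = n_asc),
    age = rep(rep(as.integer(dn$age), times = 2 * length(dn$class)),
              length(dn$disease)),
    sex = rep(rep(rep(dn$sex, each = length(dn$age)), length(dn$class)),
              length(dn$disease)),
    class = rep(rep(dn$class, each = 2 * length(dn$age)),
                length(dn$disease)),
    value = as.vector(pv))
}

scenario_to_json <- function(sc) {
  x <- unclass(sc)
  x$target_ages <- as.character(x$target_ages) # keep Inf JSON-safe
  x[!vapply(x, is.null, TRUE)]
}

scenario_from_json <- function(x) {
  x$target_ages <- if (length(x$target_ages)) as.numeric(x$target_ages)
  x$youth_max_age <- as.integer(x$youth_max_age)
  x$horizon_years <- as.integer(x$horizon_years)
  do.call(scenario_spec, x)
}

#' Write a projection result to a directory
#'
#' Emits tidy long-format CSV tables (`counts.csv`, `disease_prev.csv`,
#' `deaths.csv`, `new_cases.csv`, `exits.csv`) plus a JSON run manifest
#' recording the scenario, bundle fingerprint, and package version. The
#' compartmental engine is deterministic, so two runs of the same bundle and
#' scenario produce byte-identical files.
#'
#' @param result A `projection_result`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "projection_result"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) write_table_csv(df, file.path(path, file))
  n <- length(result$years)
  w(do.call(rbind, lapply(seq_len(n), state_df, result = result)),
    "counts.csv")
  if (length(result$disease_names)) {
    w(do.call(rbind, lapply(seq_len(n), prev_df, result = result)),
      "disease_prev.csv")
  }
  h <- n - 1L
  deaths_df <- do.call(rbind, lapply(seq_len(h), function(t) {
    tibble::tibble(year = result$years[t],
                   age = rep(0:result$age_max, 2),
                   sex = rep(SEXES, each = result$age_max + 1L),
                   value = as.vector(result$deaths[t, , ]))
  }))
  if (is.null(deaths_df)) {
    deaths_df <- tibble::tibble(year = integer(), age = integer(),
                                sex = character(), value = double())
  }
  w(deaths_df, "deaths.csv")
  if (h > 0 && length(result$disease_names)) {
    nc_df <- do.call(rbind, lapply(seq_len(h), function(t) {
      pv <- result$new_cases[[t]]
      dn <- dimnames(pv)
      n_asc <- prod(dim(pv)[1:3])
      tibble::tibble(
        year = result$years[t],
        disease = rep(dn$disease, each = n_asc),
        age = rep(rep(as.integer(dn$age), times = 2 * length(dn$class)),
                  length(dn$disease)),
        sex = rep(rep(rep(dn$sex, each = length(dn$age)), length(dn$class)),
                  length(dn$disease)),
        class = rep(rep(dn$class, each = 2 * length(dn$age)),
                    length(dn$disease)),
        value = as.vector(pv))
    }))
    w(nc_df, "new_cases.csv")
  }
  exits_df <- if (h > 0) {
    tibble::tibble(year = rep(result$years[seq_len(h)], 2),
                   sex = rep(SEXES, each = h),
                   value = as.vector(result$exits))
  } else {
    tibble::tibble(year = integer(), sex = character(), value = double())
  }
  w(exits_df, "exits.csv")
  jsonlite::write_json(
    list(format = "smokesim-result",
         package_version = as.character(packageVersion("smokesim")),
         scenario = scenario_to_json(result$scenario),
         years = result$years, age_max = result$age_max,
         k_classes = result$k_classes,
         disease_names = result$disease_names,
         baseline_year = result$baseline_year,
         bundle_checksum = result$bundle_checksum),
    file.path(path, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}

#' Reload a projection result written by [write_results()]
#'
#' @param path Directory containing the result tables and manifest.
#' @return A `projection_result` equal to the one written.
#' @export
read_results <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  am <- as.integer(mf$age_max)
  k <- as.integer(mf$k_classes)
  cls <- smoking_classes(k)
  dn <- mf$disease_names
  if (length(dn) == 0) dn <- character()
  years <- as.integer(mf$years)
  n <- length(years)
  h <- n - 1L
  rd <- function(f) read_table_csv(file.path(path, f))

  cnt_df <- rd("counts.csv")
  counts <- lapply(years, function(y) {
    d <- cnt_df[cnt_df$year == y, ]
    a <- array(NA_real_, dim = c(am + 1L, 2L, length(cls)),
               dimnames = list(age = ages_of(am), sex = SEXES, class = cls))
    a[cbind(d$age + 1L, match(d$sex, SEXES), match(d$class, cls))] <- d$count
    a
  })
  prevs <- lapply(years, function(y) {
    a <- array(0, dim = c(am + 1L, 2L, length(cls), max(length(dn), 1L)),
               dimnames = list(age = ages_of(am), sex = SEXES, class = cls,
                               disease = if (length(dn)) dn else "none"))
    a
  })
  if (length(dn)) {
    pv_df <- rd("disease_prev.csv")
    for (i in seq_len(n)) {
      d <- pv_df[pv_df$year == years[i], ]
      prevs[[i]][cbind(d$age + 1L, match(d$sex, SEXES), match(d$class, cls),
                       match(d$disease, dn))] <- d$value
    }
  }
  deaths <- array(0, dim = c(h, am + 1L, 2L),
                  dimnames = list(year = if (h) years[seq_len(h)],
                                  age = ages_of(am), sex = SEXES))
  d_df <- rd("deaths.csv")
  if (nrow(d_df)) {
    deaths[cbind(match(d_df$year, years), d_df$age + 1L,
                 match(d_df$sex, SEXES))] <- d_df$value
  }
  new_cases <- vector("list", max(h, 0L))
  if (h > 0 && length(dn) && file.exists(file.path(path, "new_cases.csv"))) {
    nc_df <- rd("new_cases.csv")
    for (t in seq_len(h)) {
      a <- array(0, dim = c(am + 1L, 2L, length(cls), length(dn)),
                 dimnames = list(age = ages_of(am), sex = SEXES, class = cls,
                                 disease = dn))
      d <- nc_df[nc_df$year == years[t], ]
      a[cbind(d$age + 1L, match(d$sex, SEXES), match(d$class, cls),
              match(d$disease, dn))] <- d$value
      new_cases[[t]] <- a
    }
  }
  exits <- matrix(0, max(h, 0L), 2L,
                  dimnames = list(if (h) years[seq_len(h)], SEXES))
  e_df <- rd("exits.csv")
  if (nrow(e_df)) {
    exits[cbind(match(e_df$year, years), match(e_df$sex, SEXES))] <- e_df$value
  }

  structure(
    list(years = years, counts = counts, prev = prevs, deaths = deaths,
         new_cases = new_cases, exits = exits,
         scenario = scenario_from_json(mf$scenario),
         age_max = am, k_classes = k, disease_names = dn,
         baseline_year = as.integer(mf$baseline_year),
         bundle_checksum = mf$bundle_checksum),
    class = "projection_result"
  )
}

#' Read / write a scenario specification file
#'
#' Scenario files are JSON (or YAML, if the `yaml` package is installed)
#' objects whose keys mirror the arguments of [scenario_spec()].
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return [read_scenario()] returns a [scenario_spec()].
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML scenario files requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scenario_from_json(x)
}

#' @rdname read_scenario
#' @param scenario A [scenario_spec()] to write.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  ext <- tolower(tools::file_ext(path))
  x <- scenario_to_json(scenario)
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("writing YAML scenario files requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}
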