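# CSV readers with strict schema validation and collected, line-numbered
# errors; plus the end-to-end orchestration.

read_checked_csv <- function(path, required, numeric_cols, positive_cols = numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      problems <- c(problems, sprintf("line %d: non-numeric %s '%s'",
                                      bad + 1L, col, df[[col]][bad]))
    }
    df[[col]] <- v
    if (col %in% positive_cols) {
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad)) {
        problems <- c(problems, sprintf("line %d: non-positive %s (%g)",
                                        bad + 1L, col, v[bad]))
      }
    }
  }
  if (length(problems)) {
    stop("malformed rows in '", path, "':\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "),
         if (length(problems) > 20) sprintf("\n  ... and %d more", length(problems) - 20),
         call. = FALSE)
  }
  df
}

#' Read longitudinal weight records
#'
#' Strictly validated CSV with header `animal_id,breed,age_days,weight_kg`;
#' malformed rows are collected and reported together with line numbers.
#'
#' @param path Path to the CSV file.
#' @return Data frame of weight records.
#' @export
read_weights <- function(path) {
  read_checked_csv(path,
                   required = c("animal_id", "breed", "age_days", "weight_kg"),
                   numeric_cols = c("age_days", "weight_kg"))
}

#' Read a slaughter trait table
#'
#' CSV with at least `animal_id,breed,body_weight` plus one or more numeric
#' trait columns.
#'
#' @param path Path to the CSV file.
#' @return Data frame, trait columns coerced to numeric.
#' @export
read_trait_table <- function(path) {
  df <- read_checked_csv(path,
                         required = c("animal_id", "breed", "body_weight"),
                         numeric_cols = "body_weight")
  traits <- setdiff(names(df), c("animal_id", "breed", "body_weight",
                                 "weight_group"))
  if (!length(traits)) {
    stop("schema error in '", path, "': no trait columns found", call. = FALSE)
  }
  for (col in traits) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Read a qPCR Ct table
#'
#' CSV with header `sample_id,group,gene,ct`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  read_checked_csv(path,
                   required = c("sample_id", "group", "gene", "ct"),
                   numeric_cols = "ct")
}

#' Per-breed landmark summary table
#'
#' One row per breed with the fitted logistic parameters, fit quality and all
#' derived landmarks — the layout of a growth-model summary table plus the
#' two maximum-deceleration columns.
#'
#' @param fits Named list of [fit_logistic()] results (names = breeds).
#' @return Data frame with columns `breed`, `n`, `pcc`, `A`, `B`, `K`,
#'   `P_BW`, `P_Age`, `MDG`, `max_decel_age`, `max_decel_weight`.
#' @export
landmark_table <- function(fits) {
  rows <- lapply(names(fits), function(b) {
    f <- fits[[b]]
    lm_ <- growth_landmarks(f$params)
    data.frame(breed = b,
               n = if (!is.na(f$n_animals)) f$n_animals else f$n_points,
               pcc = f$pcc, A = f$params$A, B = f$params$B, K = f$params$K,
               P_BW = lm_$inflection_weight, P_Age = lm_$inflection_age,
               MDG = lm_$max_daily_gain,
               max_decel_age = lm_$max_decel_age,
               max_decel_weight = lm_$max_decel_weight,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

run_stage <- function(manifest, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr, error = NULL),
                  error = function(e) list(ok = FALSE, value = NULL,
                                           error = conditionMessage(e)))
  manifest$stages[[name]] <- list(status = if (res$ok) "ok" else "failed",
                                  error = res$error)
  list(manifest = manifest, value = res$value, ok = res$ok)
}

#' Run the full growth-inflection analysis
#'
#' Orchestrates every stage on the supplied inputs: per-breed logistic fits
#' and landmark derivation; trait screening (trends, correlations,
#' clustering, PCA); post-inflection trait trajectories with plateau
#' detection; and qPCR fold changes. Stage failures are recorded in the
#' manifest and downstream dependents skipped.
#'
#' @param weights Data frame of weight records (or path, read via
#'   [read_weights()]). Optional.
#' @param traits Slaughter trait table (data frame with `weight_group`, or
#'   path). Optional.
#' @param qpcr Ct table (data frame or path). Optional.
#' @param trajectory_traits Trait columns to model against body weight.
#' @param alpha Significance level for the trend screen.
#' @param plateau_threshold Slope fraction for plateau detection.
#' @param ref_gene,calibrator qPCR reference gene and calibrator group
#'   (required when `qpcr` is given; default calibrator = first group).
#' @param out_dir Optional directory; when given, [write_report()] is called.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @return An object of class `pigrowth_report`: list with `landmarks`,
#'   `trends`, `correlations`, `pca`, `clusters`, `plateaus`,
#'   `fold_changes`, and `manifest`.
#' @export
run_full_analysis <- function(weights = NULL, traits = NULL, qpcr = NULL,
                              trajectory_traits = c("LMA", "IMF"),
                              alpha = 0.05, plateau_threshold = 0.1,
                              ref_gene = "GAPDH", calibrator = NULL,
                              out_dir = NULL, seed = NA_integer_) {
  manifest <- list(
    package = "pigrowth",
    version = as.character(utils::packageVersion("pigrowth")),
    seed = seed,
    config = list(alpha = alpha, plateau_threshold = plateau_threshold,
                  trajectory_traits = trajectory_traits,
                  ref_gene = ref_gene, calibrator = calibrator),
    stages = list()
  )
  out <- list(landmarks = NULL, trends = NULL, correlations = NULL,
              pca = NULL, clusters = NULL, plateaus = NULL,
              fold_changes = NULL)

  if (is.character(weights)) weights <- read_weights(weights)
  if (is.character(traits))  traits  <- read_trait_table(traits)
  if (is.character(qpcr))    qpcr    <- read_ct_table(qpcr)

  if (!is.null(weights)) {
    st <- run_stage(manifest, "growth_model", {
      fits <- lapply(split(weights, weights$breed), fit_logistic)
      landmark_table(fits)
    })
    manifest <- st$manifest; out$landmarks <- st$value
  }

  if (!is.null(traits)) {
    if (is.null(traits$weight_group)) {
      stop("trait table needs a 'weight_group' column (see assign_weight_groups)",
           call. = FALSE)
    }
    st <- run_stage(manifest, "trait_screen",
                    screen_traits(traits, alpha = alpha))
    manifest <- st$manifest; out$trends <- st$value

    st <- run_stage(manifest, "correlations", {
      lapply(split(traits, traits$breed), function(tb) {
        trait_correlations(tb[setdiff(names(tb), c("animal_id", "breed"))])
      })
    })
    manifest <- st$manifest; out$correlations <- st$value

    st <- run_stage(manifest, "pca", {
      lapply(split(traits, traits$breed), function(tb) {
        trait_pca(tb[setdiff(names(tb),
                             c("animal_id", "breed", "weight_group"))])
      })
    })
    manifest <- st$manifest; out$pca <- st$value

    st <- run_stage(manifest, "clustering", {
      lapply(split(traits, traits$breed), function(tb) {
        cluster_traits(group_trait_means(tb))
      })
    })
    manifest <- st$manifest; out$clusters <- st$value

    st <- run_stage(manifest, "trait_trajectory", {
      rows <- list()
      for (b in unique(traits$breed)) {
        tb <- traits[traits$breed == b, ]
        for (tr in intersect(trajectory_traits, names(tb))) {
          fit <- fit_trait_curve(tb$body_weight, tb[[tr]], "auto",
                                 trait_name = tr, breed = b)
          pl <- plateau_weight(fit, plateau_threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            breed = b, trait = tr, model_form = fit$model_form,
            aic = fit$aic, plateau_weight = pl$plateau_weight,
            max_slope = pl$max_slope, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    manifest <- st$manifest; out$plateaus <- st$value
  }

  if (!is.null(qpcr)) {
    if (is.null(calibrator)) calibrator <- sort(unique(qpcr$group))[1]
    st <- run_stage(manifest, "expression",
                    delta_delta_ct(qpcr, ref_gene, calibrator))
    manifest <- st$manifest; out$fold_changes <- st$value
  }

  failed <- vapply(manifest$stages, function(s) s$status == "failed", logical(1))
  manifest$ok <- !any(failed)
  out$manifest <- manifest
  class(out) <- "pigrowth_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.pigrowth_report <- function(x, ...) {
  cat("pigrowth analysis report\n")
  for (nm in names(x$manifest$stages)) {
    s <- x$manifest$stages[[nm]]
    cat(sprintf("  %-18s %s%s\n", nm, s$status,
                if (!is.null(s$error)) paste0(" (", s$error, ")") else ""))
  }
  if (!is.null(x$landmarks)) {
    cat("landmarks:\n"); print(x$landmarks, digits = 6)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `landmarks.csv`, `trends.csv`, per-breed `correlations_<breed>.csv`
#' and `pca_scores_<breed>.csv`, `cluster_assignments.csv`, `plateaus.csv`,
#' `fold_changes.csv`, a `manifest.json` and a short `summary.md`. Numeric
#' output is written at full precision.
#'
#' @param report A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pigrowth_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  if (!is.null(report$landmarks)) wcsv(report$landmarks, "landmarks.csv")
  if (!is.null(report$trends))    wcsv(report$trends, "trends.csv")
  for (b in names(report$correlations)) {
    wcsv(as.data.frame(report$correlations[[b]]),
         sprintf("correlations_%s.csv", b))
  }
  for (b in names(report$pca)) {
    wcsv(as.data.frame(report$pca[[b]]$scores),
         sprintf("pca_scores_%s.csv", b))
  }
  if (!is.null(report$clusters)) {
    rows <- do.call(rbind, lapply(names(report$clusters), function(b) {
      hc <- report$clusters[[b]]$hclust
      data.frame(breed = b, item = hc$labels, order = order(hc$order),
                 stringsAsFactors = FALSE)
    }))
    wcsv(rows, "cluster_assignments.csv")
  }
  if (!is.null(report$plateaus)) wcsv(report$plateaus, "plateaus.csv")
  if (!is.null(report$fold_changes)) {
    wcsv(report$fold_changes$summary, "fold_changes.csv")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  md <- c("# Growth-inflection analysis summary", "")
  if (!is.null(report$landmarks)) {
    md <- c(md, "## Growth landmarks", "",
            utils::capture.output(print(report$landmarks, digits = 6)), "")
  }
  if (!is.null(report$trends)) {
    tab <- table(report$trends$breed, report$trends$direction)
    md <- c(md, "## Trend screen", "", utils::capture.output(print(tab)), "")
  }
  if (!is.null(report$plateaus)) {
    md <- c(md, "## Trajectory plateaus", "",
            utils::capture.output(print(report$plateaus, digits = 4)), "")
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
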