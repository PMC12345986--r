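#' Relative gene expression by the 2^-ddCt (Livak) method
#'
#' For each sample, technical replicates are averaged at the Ct level, then
#' `dCt = Ct(target) - Ct(reference)`. `ddCt` subtracts the calibrator
#' group's mean `dCt` for the same gene, and the per-sample fold change is
#' `2^-ddCt`. Group summaries report the mean `ddCt`, the fold change of that
#' mean (`2^-mean(ddCt)`, so the calibrator group's fold is exactly 1 by
#' construction) and the SD of the per-sample folds.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (cycles, in (0, 45)).
#' @param reference_gene Name of the reference (housekeeping) gene; samples
#'   lacking it are dropped with a warning.
#' @param calibrator_group Group whose mean dCt anchors the comparison; must
#'   be present.
#' @return An object of class `fold_change_table`: list with `samples`
#'   (per-sample `gene`, `group`, `sample_id`, `dct`, `ddct`, `fold`) and
#'   `summary` (per gene x group `n`, `ddct`, `fold`, `sd_fold`).
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator_group) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("'ct' must be a data frame with columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0) || any(ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  if (!calibrator_group %in% ct$group) {
    stop("calibrator group '", calibrator_group, "' not present", call. = FALSE)
  }
  if (!reference_gene %in% ct$gene) {
    stop("reference gene '", reference_gene, "' not present", call. = FALSE)
  }

  # average technical replicates at the Ct level
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct, FUN = mean)

  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  miss <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(miss)) {
    warning("sample(s) without the reference gene dropped: ",
            paste(miss, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% miss, , drop = FALSE]
  }
  if (!nrow(tgt)) stop("no target-gene measurements left", call. = FALSE)

  tgt <- merge(tgt, ref, by = "sample_id", sort = FALSE)
  tgt$dct <- tgt$ct - tgt$ct_ref

  calib <- tgt[tgt$group == calibrator_group, , drop = FALSE]
  calib_mean <- tapply(calib$dct, calib$gene, mean)
  no_calib <- setdiff(unique(tgt$gene), names(calib_mean))
  if (length(no_calib)) {
    warning("gene(s) absent from the calibrator group dropped: ",
            paste(no_calib, collapse = ", "))
    tgt <- tgt[!tgt$gene %in% no_calib, , drop = FALSE]
  }

  tgt$ddct <- as.numeric(tgt$dct - calib_mean[tgt$gene])
  tgt$fold <- 2^(-tgt$ddct)
  samples <- tgt[, c("gene", "group", "sample_id", "dct", "ddct", "fold")]
  samples <- samples[order(samples$gene, samples$group, samples$sample_id), ]
  rownames(samples) <- NULL

  key <- interaction(samples$gene, samples$group, drop = TRUE)
  summ <- data.frame(
    gene    = tapply(samples$gene, key, `[`, 1),
    group   = tapply(samples$group, key, `[`, 1),
    n       = as.integer(tapply(samples$fold, key, length)),
    ddct    = as.numeric(tapply(samples$ddct, key, mean)),
    sd_fold = as.numeric(tapply(samples$fold, key, function(v) {
      if (length(v) > 1) stats::sd(v) else NA_real_
    })),
    stringsAsFactors = FALSE
  )
  summ$fold <- 2^(-summ$ddct)
  summ <- summ[order(summ$gene, summ$group),
               c("gene", "group", "n", "ddct", "fold", "sd_fold")]
  rownames(summ) <- NULL

  structure(list(samples = samples, summary = summ,
                 reference_gene = reference_gene,
                 calibrator_group = calibrator_group),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("Relative expression (2^-ddCt), reference %s, calibrator %s\n",
              x$reference_gene, x$calibrator_group))
  print(x$summary, digits = 4)
  invisible(x)
}
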