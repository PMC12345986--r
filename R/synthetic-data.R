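#' Default synthetic two-breed herd specification
#'
#' Full parameterization of the simulator. The defaults emulate the study
#' conditions the analysis assumes: a lean-type breed ("YP") with logistic
#' truth (A = 160.493 kg, B = 16.901, K = 0.022/day, 400 animals) and a
#' fat-type breed ("QYP") with truth (A = 137.948, B = 20.059, K = 0.016,
#' 126 animals); 5% between-animal asymptote CV and 2% multiplicative
#' measurement noise on weights; eight 10-kg slaughter weight groups per
#' breed (lean 80-160 kg, fat 60-140 kg) with published-style group sizes and
#' mean weights; trait responses programmed as linear, asymptotic
#' (saturating) or flat functions of body weight (10 up / 2 down for the lean
#' configuration, 15 up / 5 down for the fat one; lean loin muscle area
#' saturates near 130 kg, fat intramuscular fat near 110 kg); and qPCR Ct
#' values with additive group effects on a reference-gene backbone.
#'
#' @param n_yp,n_qyp Number of animals per breed in the longitudinal herd.
#' @param cv_asymptote Between-animal CV of the asymptotic weight.
#' @param cv_weight Multiplicative measurement-noise CV on observed weights.
#' @param seed Default seed recorded in the spec (simulators also accept an
#'   explicit seed).
#' @return An object of class `synthetic_herd_spec`: a nested list with
#'   elements `breeds`, `bins`, `traits`, `qpcr`, `seed`.
#' @export
synthetic_herd_spec <- function(n_yp = 400L, n_qyp = 126L,
                                cv_asymptote = 0.05, cv_weight = 0.02,
                                seed = 17L) {
  stopifnot(n_yp > 0, n_qyp > 0, cv_asymptote >= 0, cv_weight >= 0)
  lin  <- function(baseline, sd, direction = c("up", "down", "flat")) {
    direction <- match.arg(direction)
    slope <- switch(direction, up = 0.15 * sd, down = -0.15 * sd, flat = 0)
    list(type = "linear", baseline = baseline, slope = slope, sd = sd,
         direction = direction)
  }
  asym <- function(a, b, c, sd) {
    list(type = "asymptotic", a = a, b = b, c = c, sd = sd, direction = "up")
  }
  # saturating responses: plateau (10% of max slope) at start + log(10)/c
  c50 <- log(10) / 50  # plateau 50 kg past the range start

  traits_lean <- list(
    DP  = lin(70, 1.0, "up"),      # CW derived from DP, see simulate_slaughter
    CL1 = lin(95, 2.0, "up"),  CL2 = lin(78, 2.0, "up"),
    backfat1 = lin(35, 2.0, "up"), backfat2 = lin(25, 2.0, "up"),
    backfat3 = lin(20, 2.0, "up"), backfat4 = lin(22, 2.0, "up"),
    LMA = asym(a = 75, b = 30 / exp(-c50 * 80), c = c50, sd = 2.5), # ~130 kg
    IMF = lin(1.5, 0.35, "up"),
    LP  = lin(62, 1.2, "down"), WBC = lin(88, 1.5, "down"),
    LF  = lin(1.2, 0.3, "flat"),
    pH1 = lin(6.4, 0.05, "flat"), pH2 = lin(5.6, 0.05, "flat"),
    L1 = lin(44, 1.5, "flat"), a1 = lin(5.5, 0.5, "flat"),
    b1 = lin(6.5, 0.8, "flat"),
    L2 = lin(48, 1.5, "flat"), a2 = lin(6.5, 0.5, "flat"),
    b2 = lin(8, 0.8, "flat"),
    DL = lin(3, 0.6, "flat"), CLoss = lin(30, 2, "flat"),
    SF = lin(45, 5, "flat"), marbling = lin(2, 0.5, "flat"),
    CP = lin(22, 0.8, "flat"), Ash = lin(1.1, 0.06, "flat"),
    MC = lin(74, 1, "flat")
  )
  traits_fat <- list(
    DP  = lin(68, 1.0, "up"),
    CL1 = lin(85, 2.0, "up"),  CL2 = lin(70, 2.0, "up"),
    backfat1 = lin(40, 2.0, "up"), backfat2 = lin(30, 2.0, "up"),
    backfat3 = lin(25, 2.0, "up"), backfat4 = lin(27, 2.0, "up"),
    LMA = lin(22, 1.8, "up"),
    LF  = lin(2, 0.3, "up"),
    pH1 = lin(6.3, 0.05, "up"), pH2 = lin(5.5, 0.05, "up"),
    a1  = lin(6, 0.5, "up"),
    Ash = lin(1.0, 0.06, "up"),
    IMF = asym(a = 7.5, b = 4.5 / exp(-c50 * 60), c = c50, sd = 0.4), # ~110 kg
    LP  = lin(48, 1.2, "down"),
    L2  = lin(50, 1.5, "down"), b2 = lin(9, 0.8, "down"),
    MC  = lin(72, 1, "down"),  SF = lin(40, 5, "down"),
    L1 = lin(42, 1.5, "flat"), b1 = lin(7, 0.8, "flat"),
    a2 = lin(7, 0.5, "flat"),
    DL = lin(2.5, 0.6, "flat"), CLoss = lin(32, 2, "flat"),
    marbling = lin(3.5, 0.5, "flat"), CP = lin(21, 0.8, "flat"),
    WBC = lin(90, 1.5, "flat")
  )

  spec <- list(
    breeds = list(
      YP = list(params = logistic_params(160.493, 16.901, 0.022),
                n_animals = as.integer(n_yp),
                cv_asymptote = cv_asymptote, cv_weight = cv_weight,
                ages = seq(50, 350, by = 20)),
      QYP = list(params = logistic_params(137.948, 20.059, 0.016),
                 n_animals = as.integer(n_qyp),
                 cv_asymptote = cv_asymptote, cv_weight = cv_weight,
                 ages = seq(50, 400, by = 20))
    ),
    bins = list(
      YP = list(start = 80, width = 10, n_groups = 8L,
                group_n = c(8L, 22L, 37L, 40L, 20L, 26L, 17L, 14L),
                group_mean = c(84.93, 95.46, 104.80, 114.72,
                               123.37, 134.25, 142.88, 153.79),
                group_sd = c(2.80, 3.05, 2.72, 3.10, 2.83, 2.76, 3.10, 2.81)),
      QYP = list(start = 60, width = 10, n_groups = 8L,
                 group_n = c(7L, 6L, 6L, 17L, 11L, 6L, 12L, 8L),
                 group_mean = c(64.85, 77.48, 85.87, 94.07,
                                105.89, 113.52, 123.88, 135.53),
                 group_sd = c(3.70, 2.02, 2.60, 3.11, 3.33, 2.11, 3.12, 4.67))
    ),
    traits = list(YP = traits_lean, QYP = traits_fat),
    qpcr = list(
      reference_gene = "GAPDH",
      n_stages = 4L, n_per_group = 6L,
      ref_ct_mean = 20, ref_ct_sd = 0.2, ct_noise_sd = 0.15,
      base_dct = c(MyoD = 3, MyoG = 3.5, Mb = 2, MSTN = 5,
                   PPARG = 4, FABP4 = 2.5),
      # Ct shift per weight stage (cycles): positive = expression declines
      stage_step = list(
        YP  = c(MyoD = 0.75, MyoG = 0.75, Mb = 0.75, MSTN = -0.75,
                PPARG = -0.75, FABP4 = -0.75),
        QYP = c(MyoD = -0.75, MyoG = -0.75, Mb = -0.75, MSTN = 0.75,
                PPARG = 0.75, FABP4 = 0.75)
      )
    ),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_herd_spec"
  spec
}

#' @export
print.synthetic_herd_spec <- function(x, ...) {
  cat("Synthetic herd specification\n")
  for (b in names(x$breeds)) {
    cfg <- x$breeds[[b]]
    cat(sprintf("  %s: n = %d, A = %.3f kg, CV(A) = %.3g, CV(obs) = %.3g, ages %g-%g d\n",
                b, cfg$n_animals, cfg$params$A, cfg$cv_asymptote,
                cfg$cv_weight, min(cfg$ages), max(cfg$ages)))
  }
  cat(sprintf("  slaughter bins: %d groups of %g kg per breed; %d traits (lean), %d (fat)\n",
              x$bins[[1]]$n_groups, x$bins[[1]]$width,
              length(x$traits[[1]]), length(x$traits[[2]])))
  cat(sprintf("  qPCR: %d stages x %d samples, reference %s; seed %d\n",
              x$qpcr$n_stages, x$qpcr$n_per_group, x$qpcr$reference_gene, x$seed))
  invisible(x)
}

#' Simulate longitudinal weight records
#'
#' Each animal gets its own asymptote `A_i = A (1 + e_i)`,
#' `e_i ~ N(0, cv_asymptote^2)`; observed weights are the animal's logistic
#' curve times multiplicative noise `(1 + h)`, `h ~ N(0, cv_weight^2)`.
#' Reproducible given `seed` (the global RNG state is untouched).
#'
#' @param spec A [synthetic_herd_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return Data frame with columns `animal_id`, `breed`, `age_days`,
#'   `weight_kg`; the seed used is recorded as attribute `"seed"`.
#' @export
simulate_herd <- function(spec = synthetic_herd_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_herd_spec"))
  out <- withr::with_seed(seed, {
    parts <- lapply(names(spec$breeds), function(b) {
      cfg <- spec$breeds[[b]]
      p <- cfg$params
      n <- cfg$n_animals
      ages <- cfg$ages
      A_i <- p$A * (1 + stats::rnorm(n, 0, cfg$cv_asymptote))
      ids <- sprintf("%s_%03d", b, seq_len(n))
      m <- length(ages)
      # rows = animals, columns = ages
      mu <- outer(A_i, 1 + p$B * exp(-p$K * ages), "/")
      eta <- matrix(stats::rnorm(n * m, 0, cfg$cv_weight), n, m)
      obs <- mu * (1 + eta)
      data.frame(
        animal_id = rep(ids, each = m),
        breed = b,
        age_days = rep(ages, times = n),
        weight_kg = as.vector(t(obs)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, parts)
  })
  attr(out, "seed") <- as.integer(seed)
  out
}

# evaluate one programmed trait response at body weight bw (range start kg)
trait_response <- function(ts, bw, start) {
  switch(ts$type,
         linear = ts$baseline + ts$slope * (bw - start),
         asymptotic = ts$a - ts$b * exp(-ts$c * bw),
         stop("unknown trait response type: ", ts$type))
}

#' Simulate a slaughter trait table
#'
#' Draws body weights group by group (sizes, means and SDs from the spec's
#' bin configuration, clipped to the breed's study range), evaluates every
#' programmed trait response at the realized weight and adds Gaussian noise.
#' Carcass weight is derived as `bw * DP / 100` so dressing percentage is
#' internally consistent. A truth table of programmed directions is returned
#' alongside.
#'
#' @inheritParams simulate_herd
#' @return List with `traits` (data frame: `animal_id`, `breed`,
#'   `body_weight`, `weight_group`, `CW`, plus all programmed traits) and
#'   `truth` (data frame: `breed`, `trait`, `direction`).
#' @export
simulate_slaughter <- function(spec = synthetic_herd_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_herd_spec"))
  res <- withr::with_seed(seed, {
    parts <- lapply(names(spec$bins), function(b) {
      bin <- spec$bins[[b]]
      tr  <- spec$traits[[b]]
      bw <- unlist(lapply(seq_len(bin$n_groups), function(g) {
        stats::rnorm(bin$group_n[g], bin$group_mean[g], bin$group_sd[g])
      }))
      lo <- bin$start
      hi <- bin$start + bin$n_groups * bin$width
      bw <- pmin(pmax(bw, lo + 0.01), hi - 0.01)
      grp <- floor((bw - lo) / bin$width) + 1L
      df <- data.frame(
        animal_id = sprintf("%s_S%03d", b, seq_along(bw)),
        breed = b, body_weight = bw, weight_group = as.integer(grp),
        stringsAsFactors = FALSE
      )
      for (nm in names(tr)) {
        ts <- tr[[nm]]
        df[[nm]] <- trait_response(ts, bw, lo) +
          stats::rnorm(length(bw), 0, ts$sd)
      }
      df$CW <- df$body_weight * df$DP / 100
      df
    })
    do.call(rbind, parts)
  })
  truth <- do.call(rbind, lapply(names(spec$traits), function(b) {
    dirs <- vapply(spec$traits[[b]], `[[`, character(1), "direction")
    rbind(
      data.frame(breed = b, trait = names(dirs), direction = unname(dirs),
                 stringsAsFactors = FALSE),
      data.frame(breed = b, trait = "CW", direction = "up",
                 stringsAsFactors = FALSE)
    )
  }))
  rownames(res) <- rownames(truth) <- NULL
  attr(res, "seed") <- as.integer(seed)
  list(traits = res, truth = truth)
}

#' Simulate a qPCR Ct table
#'
#' Per sample, the reference-gene Ct is drawn `N(ref_ct_mean, ref_ct_sd^2)`;
#' each target gene's Ct is the sample's reference Ct plus the gene's base
#' dCt, plus a per-weight-stage additive shift (`stage_step` cycles per
#' stage; positive shifts mean expression declining with weight), plus
#' `N(0, ct_noise_sd^2)` noise.
#'
#' @inheritParams simulate_herd
#' @return Data frame with columns `sample_id`, `group` (breed x stage, e.g.
#'   `"YP_G1"`), `gene`, `ct`; seed recorded as attribute `"seed"`.
#' @export
simulate_qpcr <- function(spec = synthetic_herd_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_herd_spec"))
  q <- spec$qpcr
  out <- withr::with_seed(seed, {
    parts <- list()
    for (b in names(q$stage_step)) {
      steps <- q$stage_step[[b]]
      genes <- names(steps)
      for (s in seq_len(q$n_stages)) {
        grp <- sprintf("%s_G%d", b, s)
        for (i in seq_len(q$n_per_group)) {
          sid <- sprintf("%s_%02d", grp, i)
          ct_ref <- stats::rnorm(1, q$ref_ct_mean, q$ref_ct_sd)
          ct_t <- ct_ref + q$base_dct[genes] + steps * (s - 1) +
            stats::rnorm(length(genes), 0, q$ct_noise_sd)
          parts[[length(parts) + 1L]] <- data.frame(
            sample_id = sid, group = grp,
            gene = c(q$reference_gene, genes),
            ct = c(ct_ref, unname(ct_t)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, parts)
  })
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}
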