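# Cohort simulator: two-eyed subjects in three groups (healthy controls,
# NMOSD without optic neuritis history, NMOSD with optic neuritis history),
# with per-layer fractal-dimension outcomes that carry a subject-level random
# effect (inter-eye correlation), a disability score (EDSS) drawn jointly
# with the subject's superficial-plexus outcome, visual acuity, and a
# signal-quality index that exercises the quality filter.

#' Configuration of the cohort simulator
#'
#' Defaults state the emulated study design: 44 healthy controls and 34
#' NMOSD patients (13 without, 21 with optic-neuritis history), group mean
#' D_box values per capillary layer around 1.38-1.48 with within-group SDs a
#' few hundredths, inter-eye correlation 0.6, EDSS 2.57 +/- 1.16 negatively
#' correlated (-0.475) with the subject-level superficial D_box, and a
#' signal-quality index centred at 7.5 so that roughly one eye in ten falls
#' below the usual acceptance cutoff of 6.
#'
#' @param n_hc,n_nmosd_non,n_nmosd_on subject counts per group.
#' @param mean_dbox 3 x 3 numeric matrix of group means, rows
#'   `HC`, `NMOSD_NON`, `NMOSD_ON`, columns `SCP`, `DCP`, `WCP`.
#' @param sd_dbox per-layer within-group SD of D_box (length 3, all > 0).
#' @param inter_eye_corr intraclass correlation of the two eyes' D_box,
#'   in \[0, 1).
#' @param edss_mean,edss_sd EDSS distribution for patients.
#' @param edss_dbox_corr target correlation between EDSS and subject-level
#'   SCP D_box, in (-1, 1).
#' @param va_mean,va_sd named length-3 vectors (`HC`, `NON`, `ON`) for
#'   LogMAR visual acuity per eye class.
#' @param va_dbox_link latent correlation linking visual acuity to the
#'   subject effect, named (`HC`, `NMOSD`).
#' @param sq_mean,sq_sd signal-quality distribution (rounded and clamped to
#'   1..10); must leave mass below 6 so the filter is exercisable.
#' @param age_mean,age_sd named length-2 vectors (`HC`, `NMOSD`).
#' @param p_female named length-2 vector of female proportions.
#' @param seed integer RNG seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_hc = 44L, n_nmosd_non = 13L, n_nmosd_on = 21L,
                              mean_dbox = rbind(HC = c(1.43, 1.48, 1.45),
                                                NMOSD_NON = c(1.41, 1.44, 1.44),
                                                NMOSD_ON = c(1.38, 1.41, 1.42)),
                              sd_dbox = c(SCP = 0.033, DCP = 0.047, WCP = 0.028),
                              inter_eye_corr = 0.6,
                              edss_mean = 2.57, edss_sd = 1.16,
                              edss_dbox_corr = -0.475,
                              va_mean = c(HC = -0.057, NON = 0.12, ON = 0.75),
                              va_sd = c(HC = 0.06, NON = 0.15, ON = 0.50),
                              va_dbox_link = c(HC = 0.378, NMOSD = -0.445),
                              sq_mean = 7.5, sq_sd = 1.5,
                              age_mean = c(HC = 53.11, NMOSD = 52.48),
                              age_sd = c(HC = 11.83, NMOSD = 12.99),
                              p_female = c(HC = 41 / 44, NMOSD = 32 / 34),
                              seed = 1L) {
  mean_dbox <- as.matrix(mean_dbox)
  colnames(mean_dbox) <- c("SCP", "DCP", "WCP")
  rownames(mean_dbox) <- c("HC", "NMOSD_NON", "NMOSD_ON")
  stopifnot(n_hc >= 0, n_nmosd_non >= 0, n_nmosd_on >= 0,
            all(sd_dbox > 0), edss_sd > 0, all(va_sd > 0), sq_sd > 0,
            inter_eye_corr >= 0, inter_eye_corr < 1,
            abs(edss_dbox_corr) < 1, all(abs(va_dbox_link) < 1))
  structure(list(n_hc = as.integer(n_hc), n_nmosd_non = as.integer(n_nmosd_non),
                 n_nmosd_on = as.integer(n_nmosd_on), mean_dbox = mean_dbox,
                 sd_dbox = stats::setNames(sd_dbox, c("SCP", "DCP", "WCP")),
                 inter_eye_corr = inter_eye_corr, edss_mean = edss_mean,
                 edss_sd = edss_sd, edss_dbox_corr = edss_dbox_corr,
                 va_mean = va_mean, va_sd = va_sd, va_dbox_link = va_dbox_link,
                 sq_mean = sq_mean, sq_sd = sq_sd, age_mean = age_mean,
                 age_sd = age_sd, p_female = p_female, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort of two-eyed subjects
#'
#' Draws one row per eye per capillary layer. The D_box outcome decomposes
#' into a shared subject effect and eye-level noise whose variance split
#' realizes the configured inter-eye correlation; EDSS is drawn jointly with
#' the subject effect so that its correlation with the subject-level
#' (eye-averaged) SCP D_box matches `edss_dbox_corr`.
#'
#' @param config a [cohort_sim_config()].
#' @param emit_images if `TRUE`, attach (as attribute `"images"`) one
#'   [generate_vasculature()] output per eye and layer, with the branching
#'   density mapped monotonically from that eye's true D_box.
#' @param image_params [synth_vasc_params()] template used when
#'   `emit_images = TRUE` (its `branch_density` is overridden per eye).
#' @return A `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `eye`, `group`, `on_history`, `layer`, `age`, `sex`, `sq`, `edss`,
#'   `va_logmar`, `dbox_true`.
#' @export
generate_cohort <- function(config = cohort_sim_config(), emit_images = FALSE,
                            image_params = synth_vasc_params()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_sub <- config$n_hc + config$n_nmosd_non + config$n_nmosd_on
  if (n_sub == 0) stop("empty cohort: all group counts are zero")
  rho <- config$inter_eye_corr

  # calibration: cor(EDSS, eye-averaged SCP D_box) = target requires the
  # latent correlation c below; |c| > 1 means the request is infeasible
  # (non-positive-definite joint covariance).
  subj_var_frac <- sqrt(rho + (1 - rho) / 2)
  c_lat <- if (rho > 0) config$edss_dbox_corr * subj_var_frac / sqrt(rho)
           else config$edss_dbox_corr
  if (abs(c_lat) > 1)
    stop("edss_dbox_corr infeasible at this inter_eye_corr (covariance not positive definite)")

  with_local_seed(config$seed, {
    grp <- rep(c("HC", "NMOSD_NON", "NMOSD_ON"),
               c(config$n_hc, config$n_nmosd_non, config$n_nmosd_on))
    sid <- sprintf("S%03d", seq_len(n_sub))
    is_pat <- grp != "HC"
    gkey <- ifelse(is_pat, "NMOSD", "HC")
    age <- round(stats::rnorm(n_sub, config$age_mean[gkey], config$age_sd[gkey]), 1)
    age <- pmin(pmax(age, 18), 90)
    sex <- ifelse(stats::runif(n_sub) < config$p_female[gkey], "F", "M")

    z <- stats::rnorm(n_sub)              # shared subject effect
    u <- stats::rnorm(n_sub)              # EDSS residual
    edss <- ifelse(is_pat,
                   config$edss_mean + config$edss_sd *
                     (c_lat * z + sqrt(1 - c_lat^2) * u),
                   NA_real_)
    edss <- pmin(pmax(round(edss * 2) / 2, 0), 10)

    layers <- c("SCP", "DCP", "WCP")
    eyes <- c("OD", "OS")
    rows <- vector("list", 3)
    link <- ifelse(is_pat, config$va_dbox_link["NMOSD"], config$va_dbox_link["HC"])
    for (li in seq_along(layers)) {
      l <- layers[li]
      mu <- config$mean_dbox[grp, l]
      sdl <- config$sd_dbox[l]
      for (e in eyes) {
        eps <- stats::rnorm(n_sub)
        db <- mu + sdl * (sqrt(rho) * z + sqrt(1 - rho) * eps)
        on_hist <- as.integer(grp == "NMOSD_ON")
        cls <- ifelse(grp == "HC", "HC", ifelse(on_hist == 1, "ON", "NON"))
        va <- config$va_mean[cls] + config$va_sd[cls] *
          (link * z + sqrt(1 - link^2) * stats::rnorm(n_sub))
        sq <- pmin(pmax(round(stats::rnorm(n_sub, config$sq_mean, config$sq_sd)), 1), 10)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, eye = e,
          group = ifelse(grp == "HC", "HC", "NMOSD"),
          on_history = on_hist, layer = l, age = age, sex = sex,
          sq = as.integer(sq), edss = edss, va_logmar = round(va, 3),
          dbox_true = round(db, 5), stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$subject_id, tab$eye, match(tab$layer, layers)), ]
    rownames(tab) <- NULL
    class(tab) <- c("cohort_table", "data.frame")

    if (emit_images) {
      imgs <- list()
      for (i in seq_len(nrow(tab))) {
        bd <- dbox_to_branch_density(tab$dbox_true[i])
        p <- image_params
        p$branch_density <- bd
        key <- sprintf("%s_%s_%s", tab$subject_id[i], tab$eye[i], tab$layer[i])
        imgs[[key]] <- generate_vasculature(p, seed = config$seed + i,
                                            layer = tab$layer[i])
        imgs[[key]]$image$subject_id <- tab$subject_id[i]
        imgs[[key]]$image$eye <- tab$eye[i]
        imgs[[key]]$image$sq <- tab$sq[i]
      }
      attr(tab, "images") <- imgs
    }
    tab
  })
}

# monotone map from a target fractal dimension to the generator's branching
# dial; anchored so typical macular D_box values land in a sensible range
dbox_to_branch_density <- function(dbox) {
  pmax(0.05, 0.8 + 8 * (dbox - 1.40))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `cohort_table` data frame.
#' @param path CSV file.
#' @return `read_cohort_csv` returns a `cohort_table`; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "group", "on_history", "layer", "sq")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
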