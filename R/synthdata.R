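#' Configuration for the synthetic ADME/TK dataset generator
#'
#' The defaults emulate a repeat-dose study read out by untargeted
#' LC-MS: five timepoints with dosing to steady state followed by
#' washout (rise to plateau, then drop), 3 exposed and 3 control animals
#' per timepoint, pooled QCs, extract blanks; a parent drug (sunitinib's
#' molecular formula by default) detected as its protonated molecular
#' ion plus adduct/isotopologue satellites; biotransformation products
#' kinetically coupled to the parent; several hundred endogenous
#' features, some class-shifted (treatment effect, fold change capped at
#' 3) and some dose-coupled (intensity tracking the parent level);
#' blank contaminants; and intensity-dependent dropout producing the
#' missing-value pattern typical of untargeted data. Xenobiotic signals
#' are planted at >= 50-fold above the endogenous background in exposed
#' samples and entirely absent from controls and blanks.
#'
#' @param n_exposed,n_control biological replicates per timepoint (3).
#' @param n_qc,n_blank total pooled-QC and blank injections (8, 4).
#' @param timepoints ordered labels of the study days.
#' @param parent_formula molecular formula of the parent xenobiotic.
#' @param parent_rt parent retention time, seconds.
#' @param dose_profile relative parent level per timepoint
#'   (rise-to-plateau then washout).
#' @param n_products number of planted biotransformation products (8).
#' @param n_endogenous endogenous features (500).
#' @param n_class_shifted endogenous features displaced in exposed
#'   samples (30), with fold changes drawn from `shift_fold_range`.
#' @param shift_fold_range fold-change range of class-shifted features
#'   (capped at 3).
#' @param n_dose_coupled endogenous features whose intensity tracks the
#'   realised parent level (20).
#' @param n_blank_contaminants features carried by blanks (10).
#' @param xeno_intensity peak intensity of the parent in exposed samples.
#' @param base_log_mean,base_log_sd log-scale location/spread of
#'   endogenous base intensities.
#' @param cv multiplicative measurement coefficient of variation (0.1).
#' @param dropout_threshold intensity below which dropout probability
#'   rises; `dropout_rate` is its ceiling.
#' @param seed single seed driving all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_exposed = 3, n_control = 3, n_qc = 8,
                       n_blank = 4,
                       timepoints = c("d1", "d2", "d4", "d8", "d15"),
                       parent_formula = "C22H27FN4O2",
                       parent_rt = 210,
                       dose_profile = c(0.35, 0.65, 0.9, 1.0, 0.25),
                       n_products = 8, n_endogenous = 500,
                       n_class_shifted = 30,
                       shift_fold_range = c(1.5, 3),
                       n_dose_coupled = 20, n_blank_contaminants = 10,
                       xeno_intensity = 5e7, base_log_mean = log(1e5),
                       base_log_sd = 1, cv = 0.1,
                       dropout_threshold = 5e3, dropout_rate = 0.9,
                       seed = 1) {
  stopifnot(length(dose_profile) == length(timepoints),
            n_class_shifted + n_dose_coupled <= n_endogenous,
            cv >= 0, dropout_rate >= 0, dropout_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Transformation paths planted for the synthetic products; each is a
# sequence of default_rules() names so round-trip annotation can recover
# the path exactly.
planted_product_paths <- function(n_products) {
  paths <- list(
    "oxidation",
    "de-ethylation",
    "demethylation",
    "glucuronidation",
    c("oxidation", "oxidation"),
    c("de-ethylation", "oxidation"),
    "sulfation",
    c("oxidation", "glucuronidation"),
    "dehydrogenation",
    c("demethylation", "oxidation")
  )
  if (n_products > length(paths)) {
    stop("at most ", length(paths), " planted products supported")
  }
  paths[seq_len(n_products)]
}

#' Simulate a peak matrix with known ground truth
#'
#' Generates the full synthetic study: a `PeakMatrix` (features x
#' samples with intensity-dependent missingness), a ground-truth table
#' assigning every feature a role (`parent_ion`, `product_ion`,
#' `satellite`, `endogenous`, `dose_coupled`, `class_shifted`,
#' `blank_contaminant`) plus planted transformation paths and dose
#' profiles, and an MS2 library containing the parent spectrum, one
#' spectrum per product (conserved + delta-shifted parent fragments) and
#' decoy spectra sharing at most two fragments with the parent.
#'
#' Satellite m/z offsets are rule-exact ([ion_rules()] deltas) and
#' co-elute with their monoisotopic ion within 2 s, so grouping recovers
#' the planted groups at zero m/z noise; product neutral masses are
#' exact [enumerate_products()] outputs for the planted paths.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (`PeakMatrix`), `truth` (data.frame),
#'   `ms2` (list of `ms2_spectrum`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tp <- config$timepoints
  n_tp <- length(tp)
  rules <- default_rules()
  rule_by_name <- setNames(rules, vapply(rules, `[[`, "", "name"))

  # --- sample metadata ------------------------------------------------
  mk <- function(cls, n_per_tp) {
    do.call(rbind, lapply(seq_len(n_tp), function(t) {
      data.frame(
        sample_id = sprintf("%s_%s_%d", substr(cls, 1, 3), tp[t],
                            seq_len(n_per_tp)),
        class = cls,
        subject = sprintf("%s%02d", substr(cls, 1, 1),
                          (t - 1) * n_per_tp + seq_len(n_per_tp)),
        timepoint = tp[t], stringsAsFactors = FALSE)
    }))
  }
  samples <- rbind(
    mk("exposed", config$n_exposed), mk("control", config$n_control),
    data.frame(sample_id = sprintf("QC_%d", seq_len(config$n_qc)),
               class = "QC", subject = NA, timepoint = NA,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("blank_%d", seq_len(config$n_blank)),
               class = "blank", subject = NA, timepoint = NA,
               stringsAsFactors = FALSE))
  n_samp <- nrow(samples)
  is_exp <- samples$class == "exposed"
  is_ctl <- samples$class == "control"
  is_qc <- samples$class == "QC"
  is_blk <- samples$class == "blank"
  tp_of <- samples$timepoint

  noise <- function(n) exp(rnorm(n, -0.5 * log(1 + config$cv^2),
                                 sqrt(log(1 + config$cv^2))))

  # --- xenobiotic compounds -------------------------------------------
  parent_f <- parse_formula(config$parent_formula)
  parent_mass <- monoisotopic_mass(parent_f)
  paths <- planted_product_paths(config$n_products)
  prod_formulas <- lapply(paths, function(p) {
    f <- parent_f
    for (nm in p) f <- apply_rule(f, rule_by_name[[nm]])
    f
  })
  prod_masses <- vapply(prod_formulas, monoisotopic_mass, numeric(1))
  pos_rules <- ion_rules("positive")
  mh <- pos_rules[pos_rules$name == "[M+H]+", ]

  # per-sample realised parent level: dose profile x biological noise
  dose_at <- setNames(config$dose_profile, tp)
  parent_level <- rep(NA_real_, n_samp)
  bio <- is_exp
  parent_level[bio] <- config$xeno_intensity * dose_at[tp_of[bio]] *
    noise(sum(bio))
  parent_level[is_qc] <- config$xeno_intensity *
    mean(config$dose_profile) / 2 * noise(sum(is_qc))

  # product couplings and kinetic lag: later products accumulate,
  # conjugates wash out with the parent
  coupling <- runif(config$n_products, 0.1, 0.6)
  feat <- list()
  inten <- list()
  truth <- list()
  ms2 <- list()

  add_feature <- function(id, mz, rt, values, role, path = NA,
                          formula = NA, parent_id = NA, cluster = NA) {
    feat[[length(feat) + 1L]] <<- data.frame(
      feature_id = id, mz = mz, rt = rt, stringsAsFactors = FALSE)
    inten[[length(inten) + 1L]] <<- values
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_id = id, role = role, path = path, formula = formula,
      parent_feature = parent_id, cluster = cluster,
      stringsAsFactors = FALSE)
  }

  parent_id <- "P_M+H"
  parent_vals <- parent_level
  add_feature(parent_id, ion_mz(parent_mass, mh), config$parent_rt,
              parent_vals, "parent_ion", path = "parent",
              formula = format_formula(parent_f))

  # parent satellites: [M+Na]+, [M+NH4]+, 13C1 (co-eluting within 2 s)
  sat_forms <- c("[M+Na]+", "[M+NH4]+", "[M+H]+ 13C1")
  sat_frac <- c(0.25, 0.15, 0.24)
  for (s in seq_along(sat_forms)) {
    rr <- pos_rules[pos_rules$name == sat_forms[s], ]
    add_feature(sprintf("P_sat%d", s), ion_mz(parent_mass, rr),
                config$parent_rt + runif(1, -2, 2),
                parent_vals * sat_frac[s] * noise(n_samp), "satellite",
                parent_id = parent_id)
  }

  prod_ids <- sprintf("B%d_M+H", seq_len(config$n_products))
  # three kinetic shapes -> true temporal clusters
  shape_of <- rep_len(1:3, config$n_products)
  shapes <- list(
    dose_at,                                   # tracks parent
    setNames(cumsum(dose_at) / max(cumsum(dose_at)), tp),  # accumulates
    setNames(rev(dose_at), tp))                # early-peaking
  for (b in seq_len(config$n_products)) {
    lvl <- rep(NA_real_, n_samp)
    shape <- shapes[[shape_of[b]]]
    lvl[is_exp] <- config$xeno_intensity * coupling[b] *
      shape[tp_of[is_exp]] *
      (parent_level[is_exp] /
         (config$xeno_intensity * dose_at[tp_of[is_exp]])) *
      noise(sum(is_exp))
    lvl[is_qc] <- config$xeno_intensity * coupling[b] *
      mean(shape) / 2 * noise(sum(is_qc))
    rt_b <- config$parent_rt + 15 * b
    add_feature(prod_ids[b], ion_mz(prod_masses[b], mh), rt_b, lvl,
                "product_ion", path = paste(paths[[b]], collapse = " > "),
                formula = format_formula(prod_formulas[[b]]),
                parent_id = parent_id, cluster = shape_of[b])
    if (b <= 4) {
      rr <- pos_rules[pos_rules$name == "[M+H]+ 13C1", ]
      add_feature(sprintf("B%d_sat", b), ion_mz(prod_masses[b], rr),
                  rt_b + runif(1, -2, 2), lvl * 0.24 * noise(n_samp),
                  "satellite", parent_id = prod_ids[b])
    }
  }

  # --- endogenous features --------------------------------------------
  n_endo <- config$n_endogenous
  roles <- rep("endogenous", n_endo)
  roles[seq_len(config$n_class_shifted)] <- "class_shifted"
  roles[config$n_class_shifted + seq_len(config$n_dose_coupled)] <-
    "dose_coupled"
  base <- exp(rnorm(n_endo, config$base_log_mean, config$base_log_sd))
  shift_fold <- runif(config$n_class_shifted, config$shift_fold_range[1],
                      config$shift_fold_range[2])
  endo_mz <- runif(n_endo, 80, 950)
  endo_rt <- runif(n_endo, 30, 900)
  k_shift <- 0
  for (i in seq_len(n_endo)) {
    lvl <- base[i] * noise(n_samp)
    if (roles[i] == "class_shifted") {
      k_shift <- k_shift + 1
      lvl[is_exp] <- lvl[is_exp] * shift_fold[k_shift]
    } else if (roles[i] == "dose_coupled") {
      rel <- parent_level / config$xeno_intensity
      rel[!is_exp] <- NA
      lvl[is_exp] <- base[i] * (0.2 + rel[is_exp]) *
        exp(rnorm(sum(is_exp), 0, 0.03))
    }
    lvl[is_blk] <- NA
    add_feature(sprintf("E%03d", i), endo_mz[i], endo_rt[i], lvl,
                roles[i])
  }

  # --- blank contaminants ---------------------------------------------
  for (i in seq_len(config$n_blank_contaminants)) {
    b0 <- exp(rnorm(1, config$base_log_mean + 1, 0.3))
    lvl <- b0 * noise(n_samp)  # present everywhere at similar level
    add_feature(sprintf("BLK%02d", i), runif(1, 80, 950),
                runif(1, 30, 900), lvl, "blank_contaminant")
  }

  # --- assemble, then intensity-dependent dropout ---------------------
  features <- do.call(rbind, feat)
  x <- do.call(rbind, inten)
  truth <- do.call(rbind, truth)
  # xenobiotic signal never appears in controls or blanks
  xeno_rows <- truth$role %in% c("parent_ion", "product_ion", "satellite")
  x[xeno_rows, is_ctl | is_blk] <- NA
  # endogenous/contaminant features absent from blanks except contaminants
  p_drop <- config$dropout_rate *
    stats::plogis((log(config$dropout_threshold) - log(pmax(x, 1e-9))) / 0.5)
  drop <- !is.na(x) & matrix(runif(length(x)), nrow(x)) < p_drop
  x[drop] <- NA
  rownames(x) <- features$feature_id

  pm <- suppressWarnings(peak_matrix(x, features, samples))

  # --- MS2 library -----------------------------------------------------
  parent_frag_mz <- c(185.0712, 210.1028, 238.0980, 255.1247, 283.1562,
                      326.1621)
  parent_frag_int <- c(40, 25, 100, 30, 80, 55)
  ms2[[1]] <- ms2_spectrum(
    ion_mz(parent_mass, mh),
    data.frame(mz = parent_frag_mz, intensity = parent_frag_int),
    precursor_rt = config$parent_rt, purity = 0.95,
    title = parent_id)
  for (b in seq_len(config$n_products)) {
    delta <- prod_masses[b] - parent_mass
    conserved <- parent_frag_mz[1:4]
    shifted <- parent_frag_mz[5:6] + delta
    shifted <- shifted[shifted > 50]
    fr <- data.frame(mz = c(conserved, shifted),
                     intensity = c(parent_frag_int[1:4],
                                   parent_frag_int[5:6][seq_along(shifted)]))
    ms2[[length(ms2) + 1L]] <- ms2_spectrum(
      ion_mz(prod_masses[b], mh), fr,
      precursor_rt = config$parent_rt + 15 * b, purity = 0.9,
      title = prod_ids[b])
  }
  # decoys: unrelated spectra sharing at most two parent fragments
  for (d in 1:3) {
    fr <- data.frame(
      mz = sort(c(parent_frag_mz[seq_len(d %% 3)],
                  runif(5, 60, 400))),
      intensity = runif(5 + (d %% 3), 10, 100))
    ms2[[length(ms2) + 1L]] <- ms2_spectrum(
      runif(1, 150, 600), fr, precursor_rt = runif(1, 30, 900),
      purity = 0.85, title = sprintf("decoy%d", d))
  }

  list(matrix = pm, truth = truth, ms2 = ms2, config = config)
}

#' Score discovery output against simulation ground truth
#'
#' Precision and recall of a predicted xenobiotic feature-id set against
#' the planted roles `parent_ion`, `product_ion`, `satellite`.
#'
#' @param predicted_ids character vector of discovered feature ids.
#' @param truth ground-truth table from [simulate_dataset()].
#' @return list with `precision` (NA when nothing predicted), `recall`,
#'   `tp`, `fp`, `fn`.
#' @export
score_discovery <- function(predicted_ids, truth) {
  pos <- truth$feature_id[truth$role %in%
                            c("parent_ion", "product_ion", "satellite")]
  tp <- length(intersect(predicted_ids, pos))
  fp <- length(setdiff(predicted_ids, pos))
  fn <- length(setdiff(pos, predicted_ids))
  list(precision = if (length(predicted_ids)) tp / (tp + fp) else NA,
       recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn)
}

#' Simulate scaled time profiles from planted shapes
#'
#' Draws profiles from a small set of distinct kinetic shapes
#' (rise-to-plateau, accumulation, early peak and washout, ...) with
#' additive noise after unit-variance scaling — the benchmark input for
#' [elbow_kmeans()].
#'
#' @param n_per_shape profiles per shape (default 20).
#' @param n_shapes number of planted shapes (2..4, default 3).
#' @param n_timepoints timepoints per profile (default 5).
#' @param noise_sd additive noise on the scaled profiles (default 0.2).
#' @param seed random seed.
#' @return list with `profiles` (matrix) and `labels` (true shape of
#'   each profile).
#' @export
simulate_time_profiles <- function(n_per_shape = 20, n_shapes = 3,
                                   n_timepoints = 5, noise_sd = 0.2,
                                   seed = 1) {
  stopifnot(n_shapes >= 2, n_shapes <= 4)
  set.seed(seed)
  t <- seq(0, 1, length.out = n_timepoints)
  shapes <- list(
    1 - exp(-4 * t),               # rise to plateau
    t^2,                           # accumulation
    exp(-((t - 0.25) / 0.25)^2),   # early peak then washout
    1 - t                          # monotone decline
  )[seq_len(n_shapes)]
  base <- lapply(shapes, function(s) as.numeric(scale(s)))
  profiles <- do.call(rbind, lapply(seq_len(n_shapes), function(k) {
    t(replicate(n_per_shape,
                base[[k]] + rnorm(n_timepoints, 0, noise_sd)))
  }))
  rownames(profiles) <- sprintf("prof%03d", seq_len(nrow(profiles)))
  labels <- rep(seq_len(n_shapes), each = n_per_shape)
  # re-scale rows to zero mean unit variance, as the clustering expects
  profiles <- t(scale(t(profiles)))
  list(profiles = profiles, labels = setNames(labels,
                                              rownames(profiles)))
}
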