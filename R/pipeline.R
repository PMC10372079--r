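# End-to-end orchestration of the analysis stages on a set of sessions:
# spectra -> HFO detection -> phase synchrony -> entrainment -> rate
# modulation -> head-twitch detection -> Granger causality, with CSV outputs
# and a structured run log.

#' Default pipeline configuration
#'
#' All stage parameters in one place; every value is the study default and
#' can be overridden (a YAML file with the same structure is also accepted
#' by [run_pipeline()]).
#'
#' @return nested list of stage parameter blocks.
#' @export
default_run_config <- function() {
  list(
    epochs = list(baseline = c(-35 * 60, -5 * 60), drug = c(30 * 60, 60 * 60)),
    spectra = list(window_s = 8, overlap = 0.5),
    hfo = list(fit_band = c(70, 200)),
    phase = list(halfwidth = 5, reference_structure = "OB", r_min = 0.5,
                 gate = TRUE),
    entrain = list(min_spikes = 50, alpha = 0.001),
    rates = list(bin_s = 10, alpha = 0.01),
    htr = list(),
    granger = list(window_s = 0.5, order = 5, peak_min = 0.2,
                   gamma_band = c(25, 75)),
    stages = c("spectra", "hfo", "phase", "entrain", "rates", "htr", "granger")
  )
}

# structure-averaged per-window frames: average the k-th frame across pairs
.average_frames_by_window <- function(frames_by_pair) {
  nwin <- min(vapply(frames_by_pair, length, integer(1)))
  lapply(seq_len(nwin), function(w)
    average_spectrum(lapply(frames_by_pair, function(fr) fr[[w]])))
}

#' Run the full analysis pipeline on one or more sessions
#'
#' Executes, per session: bipolar derivation and IRASA spectra per structure,
#' HFO peak detection and per-epoch detection rates, phase-synchrony mapping
#' at the session's median HFO frequency, spike entrainment, firing-rate
#' modulation, head-twitch detection, and Granger causality between
#' structures. Per-stage CSV tables, a prevalence matrix across sessions and
#' a JSON run log (parameters, timings, exclusion counts) are written under
#' `out_dir`. A stage failure is recorded in the log and the run continues
#' with the remaining independent stages.
#'
#' @param sessions list of [session()] objects or container paths.
#' @param out_dir output directory.
#' @param config configuration list (see [default_run_config()]) or path to
#'   a YAML file with the same structure; partial configs are merged over
#'   the defaults.
#' @param seed RNG seed for any stochastic step.
#' @return (invisibly) list of per-session results plus the cross-session
#'   prevalence table.
#' @export
run_pipeline <- function(sessions, out_dir, config = list(), seed = 1) {
  set.seed(seed)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = seed, config = cfg, sessions = list())
  ep_base <- epoch("baseline", cfg$epochs$baseline[1], cfg$epochs$baseline[2])
  ep_drug <- epoch("drug", cfg$epochs$drug[1], cfg$epochs$drug[2])

  res <- list()
  rate_rows <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    if (is.character(s)) s <- read_session(s)
    tag <- sprintf("s%02d", si)
    slog <- list(exclusions = list())
    out <- list(session = tag, drug_class = s$drug_class)
    t_start <- proc.time()[["elapsed"]]
    structs <- unique(s$channels$structure)

    run_stage <- function(name, fun) {
      if (!(name %in% cfg$stages)) return(NULL)
      tryCatch(fun(), error = function(e) {
        slog$errors[[name]] <<- conditionMessage(e); NULL
      })
    }

    # ---- spectra + hfo (IRASA on per-epoch slices; structure-averaged) ----
    spectra <- run_stage("spectra", function() {
      inj <- if (is.na(s$injection_time)) session_duration(s) else s$injection_time
      per_struct <- list()
      for (st in structs) {
        bp <- make_bipolar(s, st)
        if (!length(bp)) next
        for (epn in c("baseline", "drug")) {
          if (is.na(s$injection_time) && epn == "drug") next
          ep <- if (epn == "baseline") ep_base else ep_drug
          frames_by_pair <- lapply(bp, function(b) {
            sl <- slice_epoch(b$series, inj, ep, fs = b$fs)
            if (!length(sl)) return(NULL)
            irasa(sl, b$fs, cfg$spectra$window_s, cfg$spectra$overlap)
          })
          frames_by_pair <- Filter(Negate(is.null), frames_by_pair)
          if (length(frames_by_pair))
            per_struct[[st]][[epn]] <- .average_frames_by_window(frames_by_pair)
        }
      }
      per_struct
    })
    if (!is.null(spectra) && "hfo" %in% cfg$stages) {
      hfo_rows <- list(); fits_all <- list()
      for (st in names(spectra)) {
        for (epn in names(spectra[[st]])) {
          frames <- spectra[[st]][[epn]]
          if (!length(frames)) next
          dr <- detection_rate(frames, cfg$hfo$fit_band)
          hfo_rows[[paste(st, epn)]] <- data.frame(
            session = tag, structure = st, epoch = epn, rate = dr$rate,
            n_windows = length(frames))
          if (epn == "drug") fits_all[[st]] <- dr$fits
        }
      }
      out$hfo <- do.call(rbind, hfo_rows)
      if (!is.null(out$hfo))
        utils::write.csv(out$hfo, file.path(out_dir, paste0(tag, "_hfo_rates.csv")),
                         row.names = FALSE)
      rate_rows[[tag]] <- out$hfo
      out$median_f0 <- tryCatch(
        median_hfo_frequency(do.call(c, fits_all)), error = function(e) NA_real_)
    }

    # ---- phase ----
    if (!is.na(out$median_f0 %||% NA_real_) && "phase" %in% cfg$stages) {
      ph <- run_stage("phase", function() {
        ana <- session_analytic(s, out$median_f0, ep = ep_drug,
                                halfwidth = cfg$phase$halfwidth)
        pt <- phase_pair_table(ana, s$channels, gate = cfg$phase$gate)
        mp <- if (cfg$phase$reference_structure %in% structs)
          structure_phase_map(pt, cfg$phase$reference_structure,
                              cfg$phase$r_min) else NULL
        list(ana = ana, pairs = pt, map = mp)
      })
      if (!is.null(ph)) {
        out$phase_pairs <- ph$pairs
        utils::write.csv(ph$pairs, file.path(out_dir, paste0(tag, "_phase_pairs.csv")),
                         row.names = FALSE)
        if (!is.null(ph$map)) {
          out$phase_map <- ph$map$map
          utils::write.csv(ph$map$map,
                           file.path(out_dir, paste0(tag, "_phase_map.csv")),
                           row.names = FALSE)
        }
        # ---- entrain (needs the analytic series) ----
        if ("entrain" %in% cfg$stages && length(s$units)) {
          t0 <- s$injection_time + ep_drug$start
          ent <- lapply(s$units, function(u) {
            st_d <- slice_epoch(u$spike_times, s$injection_time, ep_drug)
            er <- spike_entrainment(
              spike_unit(u$unit_id, st_d, u$electrode), ph$ana, s$channels,
              t0 = t0, min_spikes = cfg$entrain$min_spikes,
              alpha = cfg$entrain$alpha)
            c(unit_id = u$unit_id,
              if (isTRUE(er$skipped)) list(mu = NA, kappa = NA, p = NA,
                                           entrained = NA, reason = er$reason)
              else list(mu = er$mu, kappa = er$kappa, p = er$rayleigh_p,
                        entrained = er$entrained, reason = ""))
          })
          out$entrainment <- do.call(rbind, lapply(ent, as.data.frame))
          utils::write.csv(out$entrainment,
                           file.path(out_dir, paste0(tag, "_entrainment.csv")),
                           row.names = FALSE)
        }
      }
    }

    # ---- rates ----
    if ("rates" %in% cfg$stages && length(s$units) &&
        !is.na(s$injection_time)) {
      rt <- run_stage("rates", function() {
        rows <- lapply(s$units, function(u) {
          zr <- standardize_rates(u$spike_times, s$injection_time,
                                  cfg$rates$bin_s, ep_base, ep_drug)
          if (zr$excluded) {
            slog$exclusions[[paste0("rates_", u$unit_id)]] <<- zr$reason
            return(data.frame(unit_id = u$unit_id, mean_z_drug = NA,
                              class = NA, p = NA))
          }
          um <- unit_modulation(u$spike_times, s$injection_time,
                                cfg$rates$bin_s, ep_base, ep_drug,
                                cfg$rates$alpha)
          data.frame(unit_id = u$unit_id, mean_z_drug = zr$mean_z_drug,
                     class = um$class, p = um$p)
        })
        do.call(rbind, rows)
      })
      if (!is.null(rt)) {
        out$rates <- rt
        utils::write.csv(rt, file.path(out_dir, paste0(tag, "_rates.csv")),
                         row.names = FALSE)
      }
    }

    # ---- htr ----
    if ("htr" %in% cfg$stages && !is.null(s$accel)) {
      ht <- run_stage("htr", function() {
        idx <- htr_index(s$accel[2, ], s$fs_accel)
        detect_htr(idx)
      })
      if (!is.null(ht)) {
        out$htr <- ht
        utils::write.csv(ht, file.path(out_dir, paste0(tag, "_htr_events.csv")),
                         row.names = FALSE)
      }
    }

    # ---- granger ----
    if ("granger" %in% cfg$stages && !is.na(out$median_f0 %||% NA_real_)) {
      gr <- run_stage("granger", function() {
        entries <- list()
        combos <- utils::combn(structs, 2)
        for (k in seq_len(ncol(combos))) {
          bx <- make_bipolar(s, combos[1, k]); by <- make_bipolar(s, combos[2, k])
          if (!length(bx) || !length(by)) next
          xs <- slice_epoch(bx[[1]]$series, s$injection_time, ep_drug, fs = s$fs_lfp)
          ys <- slice_epoch(by[[1]]$series, s$injection_time, ep_drug, fs = s$fs_lfp)
          vf <- fit_var_windows(as.numeric(xs), as.numeric(ys), s$fs_lfp,
                                cfg$granger$window_s, cfg$granger$order)
          entries[[k]] <- list(gc = gc_spectrum(vf),
                               structure_x = combos[1, k],
                               structure_y = combos[2, k])
        }
        band_summary(Filter(Negate(is.null), entries), out$median_f0,
                     cfg$granger$peak_min, cfg$granger$gamma_band)
      })
      if (!is.null(gr)) {
        out$granger <- gr$summary
        utils::write.csv(gr$summary,
                         file.path(out_dir, paste0(tag, "_granger.csv")),
                         row.names = FALSE)
      }
    }

    slog$elapsed_s <- proc.time()[["elapsed"]] - t_start
    log$sessions[[tag]] <- slog
    out$phase_ana <- NULL
    res[[tag]] <- out
  }

  # ---- cross-session prevalence matrix ----
  rates_all <- do.call(rbind, rate_rows)
  if (!is.null(rates_all)) {
    classes <- unique(vapply(sessions, function(s) {
      if (is.character(s)) s <- read_session(s); s$drug_class
    }, character(1)))
    drug_class_by_tag <- vapply(seq_along(sessions), function(si) {
      s <- sessions[[si]]; if (is.character(s)) s <- read_session(s)
      s$drug_class
    }, character(1))
    names(drug_class_by_tag) <- sprintf("s%02d", seq_along(sessions))
    rates_all$condition <- ifelse(rates_all$epoch == "baseline", "baseline",
                                  drug_class_by_tag[rates_all$session])
    prev <- list()
    for (st in unique(rates_all$structure)) {
      for (cond in unique(rates_all$condition)) {
        rr <- rates_all$rate[rates_all$structure == st &
                             rates_all$condition == cond]
        if (!length(rr)) next
        prev[[paste(st, cond)]] <- data.frame(
          structure = st, condition = cond, n_sessions = length(rr),
          class = prevalence_class(rr))
      }
    }
    prev <- do.call(rbind, prev)
    utils::write.csv(prev, file.path(out_dir, "prevalence_matrix.csv"),
                     row.names = FALSE)
    res$prevalence <- prev
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
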