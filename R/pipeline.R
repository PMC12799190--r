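# End-to-end orchestration: simulate -> classify -> entropy -> windows ->
# describe -> fit -> mediate, with seed fan-out, per-stage logging, and a
# report stage assembling the result tables.

#' Pipeline configuration
#'
#' @param out_dir Directory for stage outputs (CSV + JSON); `NULL` keeps
#'   results in memory only.
#' @param seed Global seed; fanned out deterministically to per-stage seeds.
#' @param n_participants,n_sessions,session_length Simulation size (defaults
#'   are desk-scale, far below the study's 53 x 5 x 1800 s).
#' @param window Encounter window length, seconds.
#' @param profile Sampler profile for the fitting stage (`"test"` or
#'   `"full"`).
#' @param stages Character vector of enabled stages, in dependency order.
#' @param sim_args Extra arguments to [sim_config()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1,
                            n_participants = 6, n_sessions = 2,
                            session_length = 240, window = 30,
                            profile = "test",
                            stages = c("simulate", "classify", "entropy",
                                       "windows", "describe", "fit",
                                       "mediate"),
                            sim_args = list()) {
  order_all <- c("simulate", "classify", "entropy", "windows", "describe",
                 "fit", "mediate")
  stages <- order_all[order_all %in% stages]
  need <- list(classify = "simulate", entropy = "classify",
               windows = "classify", describe = "windows",
               fit = "windows", mediate = "fit")
  for (s in stages) {
    if (!is.null(need[[s]]) && !need[[s]] %in% stages)
      stop(sprintf("stage '%s' requires stage '%s'", s, need[[s]]),
           call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = n_participants, n_sessions = n_sessions,
                 session_length = session_length, window = window,
                 profile = profile, stages = stages, sim_args = sim_args),
            class = "pipeline_config")
}

.stage_log <- function(manifest, stage, seed, rows, files = character(0)) {
  digest <- if (length(files)) tools::md5sum(files) else character(0)
  manifest$stages[[stage]] <- list(stage = stage, seed = seed, rows = rows,
                                   files = files, md5 = unname(digest),
                                   time = format(Sys.time(), "%H:%M:%S"))
  manifest
}

.write_stage <- function(cfg, name, df) {
  if (is.null(cfg$out_dir)) return(character(0))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  p <- file.path(cfg$out_dir, paste0(name, ".csv"))
  utils::write.csv(df, p, row.names = FALSE)
  p
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' session simulation, fixation classification, per-session entropy,
#' encounter windows, descriptives, the five hierarchical model fits, and
#' counterfactual mediation. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A run manifest (class `pipeline_manifest`): per-stage seeds, row
#'   counts, output files and digests, plus a `results` list holding every
#'   stage's in-memory output.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(created = format(Sys.time()), seed = config$seed,
                   r_version = as.character(getRversion()),
                   stages = list(), results = list())
  res <- list()
  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sim_seed <- derive_seed(config$seed, 1)
  sc <- do.call(sim_config, c(list(
    n_participants = config$n_participants,
    n_sessions = config$n_sessions,
    session_length = config$session_length,
    seed = sim_seed), config$sim_args))

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      sessions <- list()
      conds <- agent_types()
      for (p in seq_len(config$n_participants))
        for (s in seq_len(config$n_sessions)) {
          cond <- conds[(p + s) %% 3 + 1]
          sessions[[paste(p, s)]] <- c(
            simulate_gaze_session(sc, p, s, condition = cond),
            list(participant = p, session = s, condition = cond))
        }
      res$sessions <<- sessions
      nrows <- sum(vapply(sessions, function(x) nrow(x$samples), numeric(1)))
      manifest <<- .stage_log(manifest, "simulate", sim_seed, nrows)
    })
  }
  if ("classify" %in% config$stages) {
    run_stage("classify", function() {
      logs <- lapply(res$sessions, function(ss) {
        fx <- classify_fixations(ss$samples)
        if (!nrow(fx)) return(NULL)
        fx$participant <- ss$participant
        fx$session <- ss$session
        fx$condition <- ss$condition
        fx
      })
      fixations <- do.call(rbind, logs)
      rownames(fixations) <- NULL
      res$fixations <- fixations
      f <- .write_stage(config, "fixations", fixations)
      manifest <<- .stage_log(manifest, "classify",
                              derive_seed(config$seed, 2),
                              nrow(fixations), f)
      res <<- res
    })
  }
  if ("entropy" %in% config$stages) {
    run_stage("entropy", function() {
      et <- gte_by_session(res$fixations)
      res$entropy <<- et
      f <- .write_stage(config, "entropy", et)
      manifest <<- .stage_log(manifest, "entropy",
                              derive_seed(config$seed, 3), nrow(et), f)
    })
  }
  if ("windows" %in% config$stages) {
    run_stage("windows", function() {
      encs <- lapply(res$sessions, function(ss) {
        fx <- res$fixations[res$fixations$participant == ss$participant &
                              res$fixations$session == ss$session, ]
        e <- extract_encounters(fx, c(0, config$session_length),
                                window = config$window)
        if (!nrow(e)) return(NULL)
        e <- encounter_gte(fx, e)
        e$participant <- ss$participant
        e$session <- ss$session
        e
      })
      enc <- do.call(rbind, encs)
      if (!is.null(enc)) {
        rownames(enc) <- NULL
        # encounter index per participant in onset order
        enc <- enc[order(enc$participant, enc$session, enc$onset), ]
        enc$encounter_index <- stats::ave(
          enc$onset, enc$participant, FUN = seq_along)
      }
      res$encounters <<- enc
      f <- .write_stage(config, "encounters", enc)
      manifest <<- .stage_log(manifest, "windows",
                              derive_seed(config$seed, 4),
                              if (is.null(enc)) 0 else nrow(enc), f)
    })
  }
  if ("describe" %in% config$stages) {
    run_stage("describe", function() {
      dw <- do.call(rbind, lapply(res$sessions, function(ss) {
        fx <- res$fixations[res$fixations$participant == ss$participant &
                              res$fixations$session == ss$session, ]
        accumulate_dwell(fx, ss$participant)
      }))
      agents <- dw[dw$category %in% agent_categories(), , drop = FALSE]
      if (nrow(agents)) {
        agents$agent_type <- .category_to_condition(agents$category)
        ag <- stats::aggregate(cbind(dwell = total_dwell,
                                     count = fixation_count) ~
                                 participant + object_id + agent_type,
                               data = agents, FUN = sum)
        enc <- res$encounters
        if (!is.null(enc)) {
          gsum <- stats::aggregate(gte_post ~ participant + agent_id,
                                   data = enc[!is.na(enc$gte_post), ],
                                   FUN = mean)
          ag$gte <- gsum$gte_post[match(paste(ag$participant, ag$object_id),
                                        paste(gsum$participant,
                                              gsum$agent_id))]
        } else ag$gte <- NA_real_
        res$agent_table <<- ag
        res$descriptives <<- tryCatch(describe_conditions(ag),
                                      error = function(e) NULL)
      }
      res$dwell_table <<- dw
      f <- .write_stage(config, "dwell", dw)
      manifest <<- .stage_log(manifest, "describe",
                              derive_seed(config$seed, 5), nrow(dw), f)
    })
  }
  if ("fit" %in% config$stages) {
    run_stage("fit", function() {
      mc <- mcmc_profile(config$profile)
      fit_seed <- derive_seed(config$seed, 6)
      fits <- list()
      # dwell: per-object dwell; buildings inherit the session condition
      dw <- res$dwell_table
      fx <- res$fixations
      dw$session <- fx$session[match(paste(dw$participant, dw$object_id),
                                     paste(fx$participant, fx$object_id))]
      dw$condition <- fx$condition[match(paste(dw$participant,
                                               dw$object_id),
                                         paste(fx$participant,
                                               fx$object_id))]
      dd <- dw[dw$category %in% c("building", "task_residential",
                                  "task_public", agent_categories()), ]
      dd$object_kind <- ifelse(dd$category %in% agent_categories(),
                               "agent", "building")
      dd$agent_type <- ifelse(dd$object_kind == "agent",
                              .category_to_condition(dd$category),
                              dd$condition)
      dd$dwell <- dd$total_dwell
      fits$dwell <- fit_model(model_spec("dwell"), dd, mc, seed = fit_seed)
      # prepost: long pre/post entropies over encounters
      enc <- res$encounters
      long <- rbind(
        data.frame(participant = enc$participant, session = enc$session,
                   prepost = 0, encounter_index = enc$encounter_index,
                   H = enc$gte_pre),
        data.frame(participant = enc$participant, session = enc$session,
                   prepost = 1, encounter_index = enc$encounter_index,
                   H = enc$gte_post))
      long <- long[!is.na(long$H), ]
      long$H_star <- sv_transform(long$H, nrow(long))
      fits$prepost <- fit_model(model_spec("prepost"), long, mc,
                                seed = fit_seed + 1)
      # postgte: post windows with agent condition
      post <- data.frame(participant = enc$participant,
                         session = enc$session,
                         agent_type = enc$agent_type, H = enc$gte_post)
      post <- post[!is.na(post$H), ]
      post$H_star <- sv_transform(post$H, nrow(post))
      fits$postgte <- fit_model(model_spec("postgte"), post, mc,
                                seed = fit_seed + 2)
      # perf + mediator: linked pointing trials (simulated test session)
      md <- simulate_mediation_dataset(
        sc, n = max(300, 10 * config$n_participants),
        seed = derive_seed(config$seed, 7))
      med <- md$mediator
      med$M_star <- sv_transform(med$gte_post, nrow(med))
      fits$mediator <- fit_model(model_spec("mediator"), med, mc,
                                 seed = fit_seed + 3)
      fits$perf <- fit_model(model_spec("perf"), md$trials, mc,
                             seed = fit_seed + 4)
      res$trials <<- md$trials
      res$fits <<- fits
      summaries <- do.call(rbind, lapply(names(fits), function(nm) {
        s <- summarize_posterior(fits[[nm]])
        s$model <- nm
        s
      }))
      res$fit_summaries <<- summaries
      f <- .write_stage(config, "fit_summaries", summaries)
      manifest <<- .stage_log(manifest, "fit", fit_seed, nrow(summaries), f)
    })
  }
  if ("mediate" %in% config$stages) {
    run_stage("mediate", function() {
      w_pub <- mean(res$trials$building_type == "public")
      med_seed <- derive_seed(config$seed, 8)
      eff <- run_mediation(res$fits$mediator, res$fits$perf,
                           w_res = 1 - w_pub, w_pub = w_pub,
                           R = if (config$profile == "full") 4000 else 500,
                           seed = med_seed)
      res$mediation <<- eff
      tab <- do.call(rbind, lapply(names(eff), function(nm) {
        s <- eff[[nm]]$summary
        s$contrast <- nm
        s
      }))
      f <- .write_stage(config, "mediation", tab)
      manifest <<- .stage_log(manifest, "mediate", med_seed, nrow(tab), f)
    })
  }
  manifest$results <- res
  structure(manifest, class = "pipeline_manifest")
}

#' Assemble report tables from a pipeline run
#'
#' @param manifest A `pipeline_manifest` from [run_pipeline()].
#' @return Named list of data frames: `dwell_summary` (per condition/kind),
#'   `entropy_by_session`, `prepost_entropy`, `coefficients` (per model,
#'   with back-transformed effect column), `mediation` (additive and ratio
#'   scales). Stages that did not run yield `NULL` entries.
#' @export
pipeline_report <- function(manifest) {
  stopifnot(inherits(manifest, "pipeline_manifest"))
  res <- manifest$results
  out <- list(dwell_summary = NULL, entropy_by_session = NULL,
              prepost_entropy = NULL, coefficients = NULL, mediation = NULL)
  if (!is.null(res$dwell_table)) {
    dw <- res$dwell_table
    dw$kind <- ifelse(dw$category %in% agent_categories(), "agent",
                      "building")
    out$dwell_summary <- stats::aggregate(
      total_dwell ~ category + kind, data = dw,
      FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  }
  out$entropy_by_session <- res$entropy
  if (!is.null(res$encounters)) {
    e <- res$encounters
    ok <- !is.na(e$gte_pre) & !is.na(e$gte_post)
    out$prepost_entropy <- data.frame(
      n_encounters = sum(ok),
      mean_gte_pre = mean(e$gte_pre[ok]),
      mean_gte_post = mean(e$gte_post[ok]),
      mean_shift = mean(e$gte_post[ok] - e$gte_pre[ok]))
  }
  if (!is.null(res$fit_summaries)) {
    cf <- res$fit_summaries
    link <- ifelse(cf$model %in% c("dwell", "perf"), "log", "logit")
    cf$effect <- ifelse(link == "log",
                        100 * (exp(cf$mean) - 1),  # percent change
                        exp(cf$mean))              # odds ratio
    cf$effect_scale <- ifelse(link == "log", "percent_change", "odds_ratio")
    out$coefficients <- cf
  }
  if (!is.null(res$mediation)) {
    out$mediation <- do.call(rbind, lapply(names(res$mediation),
                                           function(nm) {
      s <- res$mediation[[nm]]$summary
      s$contrast <- nm
      s
    }))
  }
  out
}
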