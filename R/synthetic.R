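# Synthetic data generators: modular weighted connectomes and behavioral
# trial tables with the statistical structure the analysis assumes.

#' Configuration for the synthetic connectome generator
#'
#' Describes a weighted stochastic-block network standing in for a
#' single-subject anatomical connectome: `n_nodes` regions split into
#' `n_modules` near-equal planted modules, an edge present with
#' probability `p_in` within modules and `p_out` between them, and
#' nonzero streamline densities drawn from a log-normal law (positive,
#' right-skewed, like streamline counts).
#'
#' @param n_nodes number of regions (default 111, matching the anatomical
#'   parcellation the pipeline emulates).
#' @param n_modules number of planted modules (default 4).
#' @param p_in,p_out within/between-module edge probabilities; must
#'   satisfy `0 <= p_out < p_in <= 1` (defaults 0.5 / 0.0625, an 8:1
#'   contrast).
#' @param weight_meanlog,weight_sdlog log-normal parameters of nonzero
#'   weights (defaults 3 and 0.5).
#' @param seed integer RNG seed.
#' @return An object of class `"connectome_gen_config"`.
#' @export
connectome_gen_config <- function(n_nodes = 111L, n_modules = 4L,
                                  p_in = 0.5, p_out = 0.0625,
                                  weight_meanlog = 3, weight_sdlog = 0.5,
                                  seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_modules <- as.integer(n_modules)
  if (n_modules < 2L) stop("`n_modules` must be >= 2", call. = FALSE)
  if (n_nodes < 2L * n_modules) {
    stop("`n_nodes` must be >= 2 * n_modules", call. = FALSE)
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("edge probabilities must satisfy 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (weight_sdlog < 0) stop("`weight_sdlog` must be >= 0", call. = FALSE)
  structure(list(n_nodes = n_nodes, n_modules = n_modules,
                 p_in = p_in, p_out = p_out,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 seed = as.integer(seed)),
            class = "connectome_gen_config")
}

#' Generate a synthetic modular weighted connectome
#'
#' Draws a weighted stochastic-block network from `cfg`: symmetric, zero
#' diagonal, log-normal weights on present edges.  The planted module
#' labels are attached as `attr(, "planted_modules")`.  Identical seeds
#' give identical networks.
#'
#' @param cfg a [connectome_gen_config()].
#' @return A `"connectome"` (target index 1) with planted-module
#'   attribute.
#' @export
#' @examples
#' conn <- generate_connectome(connectome_gen_config(n_nodes = 20, seed = 7))
#' table(attr(conn, "planted_modules"))
generate_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "connectome_gen_config"))
  n <- cfg$n_nodes
  mods <- sort(rep_len(seq_len(cfg$n_modules), n))
  A <- with_seed(cfg$seed, {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    ij <- arrayInd(ut, c(n, n))
    p <- ifelse(mods[ij[, 1L]] == mods[ij[, 2L]], cfg$p_in, cfg$p_out)
    present <- runif(length(ut)) < p
    w <- numeric(length(ut))
    w[present] <- rlnorm(sum(present), cfg$weight_meanlog, cfg$weight_sdlog)
    W[ut] <- w
    W + t(W)
  })
  conn <- connectome(A, target = 1L)
  attr(conn, "planted_modules") <- mods
  conn
}

default_trial_coefficients <- function() {
  list(
    intercept = 7.48,
    task = -0.49,                      # sentence completion vs verb generation
    session = -0.022,                  # post vs pre, verb generation
    session_task = 0.094,              # session effect difference for SC
    stimulation = -0.022,              # active vs sham
    stimulation_session = 0.009,
    stimulation_session_task = -0.101, # TMS speeding specific to SC
    entropy = 0.155,                   # selection cost
    association = -0.666,              # retrieval ease
    boundary = -0.001,
    stimulation_boundary = 0.003,
    session_boundary = 0,
    stimulation_session_boundary = -0.002,
    boundary_entropy = 0.001,
    modal = 0,
    modal_entropy = 0,
    boundary_association = 0,
    modal_association = 0,
    task_entropy = 0,
    task_association = 0,
    trial_order = 0,
    trial_entropy = 0
  )
}

#' Configuration for the synthetic behavioral generator
#'
#' Describes a two-arm (active/sham), two-session (pre/post), two-task
#' (sentence completion / verb generation) trial-level experiment on the
#' natural-log response-time scale.  The fixed-effect structure mirrors
#' the moderation models the package fits: indicator coding with reference
#' levels sham / pre / verb_generation, continuous item covariates
#' `entropy` (selection demand) and `association` (retrieval ease) drawn
#' from Beta laws on \[0, 1\], and a continuous per-subject controllability
#' value entering main effects and interactions.  Log RTs get a Gaussian
#' subject intercept, a Gaussian per-subject slope on trial order, and a
#' Gaussian residual; a configurable share of trials is replaced by
#' fast/slow contaminants (outside the 200-10,000 ms analysis window) or
#' flagged as response errors.
#'
#' Coefficient names accepted in `coefficients` (any subset; the rest keep
#' their defaults): `intercept`, `task`, `session`, `session_task`,
#' `stimulation`, `stimulation_session`, `stimulation_session_task`,
#' `entropy`, `association`, `boundary`, `stimulation_boundary`,
#' `session_boundary`, `stimulation_session_boundary`, `boundary_entropy`,
#' `modal`, `modal_entropy`, `boundary_association`, `modal_association`,
#' `task_entropy`, `task_association`, `trial_order`, `trial_entropy`.
#' Defaults follow the effect magnitudes of the moderation analysis the
#' generator emulates (e.g. session slowing 0.072 on sentence completion,
#' TMS-by-session speeding about -0.092 there, three-way
#' stimulation-session-boundary -0.002 per boundary-rank unit).
#'
#' @param n_active,n_sham subjects per arm (defaults 25 and 16).
#' @param n_trials trials per task per session (default 50).
#' @param coefficients named list overriding any default coefficient.
#' @param subj_intercept_sd SD of the subject random intercept (log-RT
#'   units; default 0.12).
#' @param trial_slope_sd SD of the per-subject random slope on trial order
#'   (log-RT units per trial; default 0.002).
#' @param residual_sd residual SD (default 0.35).
#' @param error_rate probability a trial is flagged as a response error
#'   (default 0.045).
#' @param fast_rate,slow_rate probabilities a trial's RT is replaced by a
#'   fast (< 200 ms) or slow (> 10,000 ms) contaminant (defaults 0.005).
#' @param entropy_shape,association_shape Beta shape pairs for the item
#'   covariates (defaults `c(2, 2)`).
#' @param tasks tasks to generate (default both).
#' @param seed integer RNG seed.
#' @return An object of class `"behavior_gen_config"`.
#' @export
behavior_gen_config <- function(n_active = 25L, n_sham = 16L, n_trials = 50L,
                                coefficients = list(),
                                subj_intercept_sd = 0.12,
                                trial_slope_sd = 0.002,
                                residual_sd = 0.35,
                                error_rate = 0.045,
                                fast_rate = 0.005, slow_rate = 0.005,
                                entropy_shape = c(2, 2),
                                association_shape = c(2, 2),
                                tasks = c("sentence_completion",
                                          "verb_generation"),
                                seed = 1L) {
  beta <- default_trial_coefficients()
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown)) {
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  beta[names(coefficients)] <- coefficients
  sds <- c(subj_intercept_sd, trial_slope_sd, residual_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  rates <- c(error_rate, fast_rate, slow_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  tasks <- match.arg(tasks, c("sentence_completion", "verb_generation"),
                     several.ok = TRUE)
  if (n_active + n_sham < 1L) stop("no subjects requested", call. = FALSE)
  structure(list(n_active = as.integer(n_active), n_sham = as.integer(n_sham),
                 n_trials = as.integer(n_trials), coefficients = beta,
                 subj_intercept_sd = subj_intercept_sd,
                 trial_slope_sd = trial_slope_sd, residual_sd = residual_sd,
                 error_rate = error_rate, fast_rate = fast_rate,
                 slow_rate = slow_rate, entropy_shape = entropy_shape,
                 association_shape = association_shape, tasks = tasks,
                 seed = as.integer(seed)),
            class = "behavior_gen_config")
}

#' Generate a synthetic trial table
#'
#' Builds the full subject x task x session x trial grid, draws item
#' covariates per task (items are split between sessions and shared across
#' subjects, with per-subject randomized presentation order), evaluates
#' the linear predictor of `cfg` on the log scale, adds subject random
#' effects and residual noise, exponentiates to milliseconds, and injects
#' contaminant and error trials at the configured rates.
#'
#' @param cfg a [behavior_gen_config()].
#' @param boundary_values numeric vector with one boundary-controllability
#'   value per subject (active subjects first, then sham) — typically the
#'   zero-centered target-node ranks from [boundary_controllability()].
#' @param modal_values optional per-subject modal-controllability values;
#'   standard-normal draws when `NULL`.
#' @return data.frame with columns `subject`, `group`, `session`, `task`,
#'   `trial_order`, `item_id`, `entropy`, `association`, `boundary`,
#'   `modal`, `rt_ms`, `is_error`.
#' @seealso [preprocess_trials()], [fit_rt_model()]
#' @export
generate_trials <- function(cfg, boundary_values, modal_values = NULL) {
  stopifnot(inherits(cfg, "behavior_gen_config"))
  n_sub <- cfg$n_active + cfg$n_sham
  boundary_values <- as.numeric(boundary_values)
  if (length(boundary_values) != n_sub) {
    stop(sprintf("`boundary_values` has length %d but there are %d subjects",
                 length(boundary_values), n_sub), call. = FALSE)
  }
  b <- cfg$coefficients
  with_seed(cfg$seed, {
    if (is.null(modal_values)) {
      modal_values <- rnorm(n_sub)
    } else if (length(modal_values) != n_sub) {
      stop("`modal_values` must have one value per subject", call. = FALSE)
    }
    subjects <- sprintf("S%03d", seq_len(n_sub))
    group <- rep(c("active", "sham"), c(cfg$n_active, cfg$n_sham))

    # item pool per task: 2 * n_trials items, first half shown pre, second
    # half post, identical across subjects
    n_items <- 2L * cfg$n_trials
    item_pool <- lapply(cfg$tasks, function(tk) {
      data.frame(task = tk,
                 item_id = sprintf("%s_%03d",
                                   ifelse(tk == "sentence_completion", "SC", "VG"),
                                   seq_len(n_items)),
                 session = rep(c("pre", "post"), each = cfg$n_trials),
                 entropy = rbeta(n_items, cfg$entropy_shape[1L],
                                 cfg$entropy_shape[2L]),
                 association = rbeta(n_items, cfg$association_shape[1L],
                                     cfg$association_shape[2L]),
                 stringsAsFactors = FALSE)
    })
    item_pool <- do.call(rbind, item_pool)

    u0 <- rnorm(n_sub, 0, cfg$subj_intercept_sd)
    u1 <- rnorm(n_sub, 0, cfg$trial_slope_sd)

    rows <- vector("list", n_sub * length(cfg$tasks) * 2L)
    k <- 0L
    for (s in seq_len(n_sub)) {
      for (tk in cfg$tasks) {
        for (ss in c("pre", "post")) {
          items <- item_pool[item_pool$task == tk & item_pool$session == ss, ]
          items <- items[sample.int(nrow(items)), ]   # presentation order
          k <- k + 1L
          rows[[k]] <- data.frame(subject = subjects[s], group = group[s],
                                  session = ss, task = tk,
                                  trial_order = seq_len(cfg$n_trials),
                                  item_id = items$item_id,
                                  entropy = items$entropy,
                                  association = items$association,
                                  boundary = boundary_values[s],
                                  modal = modal_values[s],
                                  subj = s,
                                  stringsAsFactors = FALSE)
        }
      }
    }
    d <- do.call(rbind, rows)

    stim <- as.numeric(d$group == "active")
    post <- as.numeric(d$session == "post")
    sc <- as.numeric(d$task == "sentence_completion")
    lp <- b$intercept +
      b$task * sc +
      b$session * post +
      b$session_task * post * sc +
      b$stimulation * stim +
      b$stimulation_session * stim * post +
      b$stimulation_session_task * stim * post * sc +
      b$entropy * d$entropy +
      b$association * d$association +
      b$task_entropy * sc * d$entropy +
      b$task_association * sc * d$association +
      b$boundary * d$boundary +
      b$stimulation_boundary * stim * d$boundary +
      b$session_boundary * post * d$boundary +
      b$stimulation_session_boundary * stim * post * d$boundary +
      b$boundary_entropy * d$boundary * d$entropy +
      b$modal * d$modal +
      b$modal_entropy * d$modal * d$entropy +
      b$boundary_association * d$boundary * d$association +
      b$modal_association * d$modal * d$association +
      b$trial_order * d$trial_order +
      b$trial_entropy * d$trial_order * d$entropy
    log_rt <- lp + u0[d$subj] + u1[d$subj] * d$trial_order +
      rnorm(nrow(d), 0, cfg$residual_sd)
    d$rt_ms <- exp(log_rt)

    # contaminants: fast (< 200 ms), then slow (> 10,000 ms) on the rest
    r <- runif(nrow(d))
    fast <- r < cfg$fast_rate
    slow <- !fast & r < cfg$fast_rate + cfg$slow_rate
    d$rt_ms[fast] <- runif(sum(fast), 50, 199)
    d$rt_ms[slow] <- runif(sum(slow), 10001, 15000)
    d$is_error <- runif(nrow(d)) < cfg$error_rate
    d$subj <- NULL
    rownames(d) <- NULL
    d
  })
}

#' Write a trial table as headered TSV
#'
#' @param trials data.frame from [generate_trials()] (or the same
#'   columns).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(trials, path) {
  write_tsv_full(trials, path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path TSV path.
#' @return data.frame of trials.
#' @export
read_trials <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("is_error" %in% names(d)) d$is_error <- as.logical(d$is_error)
  d
}
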