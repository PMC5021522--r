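# Session persistence: tidy CSV trace file + JSON sidecar with parameters,
# ground truth and the calcium trace.

SESSION_FORMAT_VERSION <- "1.0"

#' Write / read a simulated session
#'
#' A session is stored as two plain-text files in `dir`: `traces.csv` (one
#' row per sample: `cycle`, `time_s`, `force_pN`, `probe_nm`, `target_nm`;
#' only if traces were rendered) and `session.json` (versioned header,
#' simulation parameters, per-cycle ground truth, calcium trace). The
#' round-trip is lossless for all numeric fields.
#'
#' @param session a `"bfp_session"` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @return `write_session`: `dir`, invisibly. `read_session`: a
#'   `"bfp_session"` list (cycle traces restored when `traces.csv` is
#'   present; `params` and `coupling` restored with their classes).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "bfp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  has_traces <- !is.null(session$cycles[[1]]$trace)
  if (has_traces) {
    tr <- do.call(rbind, lapply(seq_along(session$cycles), function(i) {
      cbind(cycle = i, session$cycles[[i]]$trace)
    }))
    utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  }
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    seed = session$seed,
    duration = session$duration,
    has_traces = has_traces,
    params = unclass(session$params),
    coupling = unclass(session$coupling),
    cycles = lapply(seq_along(session$cycles), function(i) {
      tru <- session$cycles[[i]]$truth
      list(cycle = i, start_time = session$cycles[[i]]$start_time,
           outcome = tru$outcome, bond_formed = tru$bond_formed,
           t_b = tru$t_b, rupture_force = tru$rupture_force,
           lrrd_unfolded = tru$lrrd_unfolded, msd_unfolded = tru$msd_unfolded,
           events = tru$events)
    }),
    calcium = session$calcium
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  jpath <- file.path(dir, "session.json")
  if (!file.exists(jpath)) stop("no session.json in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(jpath, simplifyVector = FALSE)
  if (is.null(meta$format_version))
    stop("session.json: missing format_version header", call. = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  traces <- NULL
  if (isTRUE(meta$has_traces)) {
    cpath <- file.path(dir, "traces.csv")
    if (!file.exists(cpath)) stop("session declares traces but traces.csv is missing",
                                  call. = FALSE)
    tr <- utils::read.csv(cpath)
    required <- c("cycle", "time_s", "force_pN", "probe_nm", "target_nm")
    miss <- setdiff(required, names(tr))
    if (length(miss))
      stop("traces.csv: missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    traces <- split(tr[required[-1]], tr$cycle)
  }
  params <- meta$params
  params$lifetime_model <- lapply(params$lifetime_model, function(g)
    lapply(g, as.numeric))
  params$ramped_event_probs <- unlist(params$ramped_event_probs)
  params$unfold_lengths <- lapply(params$unfold_lengths, function(u) {
    v <- unlist(u); names(v) <- c("mean", "sd"); v })
  if (is.list(params$tether) && length(params$tether) == 1 &&
      is.character(params$tether[[1]])) params$tether <- params$tether[[1]]
  class(params) <- "sim_params"
  coupling <- meta$coupling
  coupling$alpha_amp <- unlist(coupling$alpha_amp)
  coupling$beta_amp <- unlist(coupling$beta_amp)
  class(coupling) <- "calcium_coupling"
  k <- params$spring_constant
  cycles <- lapply(meta$cycles, function(cy) {
    truth <- list(bond_formed = isTRUE(cy$bond_formed), outcome = cy$outcome,
                  t_b = num_or_na(cy$t_b),
                  rupture_force = num_or_na(cy$rupture_force),
                  lrrd_unfolded = isTRUE(cy$lrrd_unfolded),
                  msd_unfolded = isTRUE(cy$msd_unfolded),
                  events = lapply(cy$events, function(e)
                    list(phase = e$phase, domain = e$domain,
                         length = as.numeric(e$length),
                         force = num_or_na(e$force), t_u = num_or_na(e$t_u))))
    tr <- if (!is.null(traces)) {
      x <- traces[[as.character(cy$cycle)]]
      rownames(x) <- NULL
      attr(x, "spring_constant") <- k
      attr(x, "sample_rate") <- params$sample_rate
      attr(x, "ramp_rate") <- params$ramp_rate
      attr(x, "clamp_force") <- params$clamp_force
      attr(x, "mode") <- params$mode
      x
    } else NULL
    structure(list(truth = truth, trace = tr, params = params,
                   start_time = as.numeric(cy$start_time)),
              class = "bfp_cycle")
  })
  tab <- do.call(rbind, lapply(seq_along(cycles), function(i) {
    cy <- meta$cycles[[i]]
    ev <- cycles[[i]]$truth$events
    clamped <- vapply(ev, function(e) e$phase == "clamped", logical(1))
    t_att <- if (cy$outcome == "lifetime")
      attain_time(cycles[[i]]$truth, params) else NA_real_
    data.frame(cycle = i, start_time = as.numeric(cy$start_time),
               outcome = cy$outcome, t_b = num_or_na(cy$t_b),
               t_end = if (identical(cy$outcome, "lifetime"))
                 as.numeric(cy$start_time) + t_att + num_or_na(cy$t_b)
               else NA_real_,
               lrrd_unfolded = isTRUE(cy$lrrd_unfolded),
               msd_unfolded = isTRUE(cy$msd_unfolded),
               msd_clamped = any(clamped),
               msd_clamp_time = if (any(clamped))
                 as.numeric(cy$start_time) + t_att + ev[clamped][[1]]$t_u
               else NA_real_)
  }))
  ca <- meta$calcium
  calcium <- list(time = as.numeric(unlist(ca$time)),
                  intensity = as.numeric(unlist(ca$intensity)),
                  truth = list(calcium_type = ca$truth$calcium_type,
                               onset_time = num_or_na(ca$truth$onset_time),
                               amplitude = num_or_na(ca$truth$amplitude)))
  structure(list(cycles = cycles, cycle_table = tab, calcium = calcium,
                 params = params, coupling = coupling,
                 seed = as.integer(meta$seed),
                 duration = as.numeric(meta$duration)),
            class = "bfp_session")
}

#' Streamed checksum of a session trace file
#'
#' Reads `traces.csv` in fixed-size line chunks (never holding the full file
#' in memory) and accumulates the sample count and the sum of the force
#' column -- a cheap integrity check for large trace files.
#'
#' @param path path to a `traces.csv` file.
#' @param chunk_lines lines per chunk (default 10000).
#' @return list with `n_samples` and `force_sum`.
#' @export
session_checksum <- function(path, chunk_lines = 10000) {
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- strsplit(readLines(con, n = 1), ",")[[1]]
  header <- gsub('"', "", header)
  fcol <- match("force_pN", header)
  if (is.na(fcol)) stop("traces.csv: missing column force_pN", call. = FALSE)
  n <- 0L; s <- 0
  repeat {
    lines <- readLines(con, n = chunk_lines)
    if (!length(lines)) break
    vals <- vapply(strsplit(lines, ","), function(x) as.numeric(x[fcol]),
                   numeric(1))
    n <- n + length(vals); s <- s + sum(vals)
  }
  list(n_samples = n, force_sum = s)
}
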