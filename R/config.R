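config_sections <- c("model", "protocol", "network", "classifier", "seeds")

model_keys <- function(type) {
  fn <- if (type == "madexp") madexp_params else elif_params
  c("type", names(formals(fn)))
}

#' Load and validate a configuration file
#'
#' Configurations are YAML with up to five sections: `model` (parameter
#' key-values, `type: elif` or `type: madexp`, fields named exactly as in
#' [elif_params()] / [madexp_params()]), `protocol` (fields of
#' [protocol()]; an empty/missing section defaults to a 1 s zero-current
#' run), `network` (fields of [network_spec()]), `classifier` (fields of
#' [behavior_thresholds()]) and `seeds`. Unknown keys and invariant
#' violations are rejected with the offending name.
#'
#' @param path path to a YAML configuration file.
#' @return object of class `metaneuron_config`: list with elements
#'   `model` (a `neuron_params`), `protocol` (a [protocol()]), `network`
#'   (a [network_spec()] or `NULL`), `classifier` (thresholds list) and
#'   `seeds` (named list).
#' @seealso [load_preset()], [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$model)) stop("config needs a model section", call. = FALSE)
  m <- raw$model
  type <- m$type %||% "elif"
  if (!type %in% c("elif", "madexp"))
    stop("model type must be 'elif' or 'madexp'", call. = FALSE)
  unknown <- setdiff(names(m), model_keys(type))
  if (length(unknown))
    stop("unknown model key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m$type <- NULL
  model <- do.call(if (type == "madexp") madexp_params else elif_params, m)

  pr <- raw$protocol
  proto <- if (is.null(pr) || !length(pr)) protocol(1000) else {
    unknown <- setdiff(names(pr), c("duration", "segments", "poisson",
                                    "alpha_schedule"))
    if (length(unknown))
      stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    protocol(duration = pr$duration %||% 1000,
             segments = if (!is.null(pr$segments))
               do.call(rbind, lapply(pr$segments, as.data.frame)),
             poisson = pr$poisson,
             alpha_schedule = if (!is.null(pr$alpha_schedule))
               do.call(rbind, lapply(pr$alpha_schedule, as.data.frame)))
  }

  net <- NULL
  if (!is.null(raw$network)) {
    nw <- raw$network
    unknown <- setdiff(names(nw), names(formals(network_spec)))
    if (length(unknown))
      stop("unknown network key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (!is.null(nw$homeostasis))
      nw$homeostasis <- do.call(rbind, lapply(nw$homeostasis,
                                              as.data.frame))
    if (!is.null(nw$stimulus) && !is.null(nw$stimulus$window))
      nw$stimulus$window <- as.numeric(unlist(nw$stimulus$window))
    net <- do.call(network_spec, nw)
  }

  cl <- raw$classifier
  thresholds <- if (is.null(cl)) behavior_thresholds() else {
    unknown <- setdiff(names(cl), names(formals(behavior_thresholds)))
    if (length(unknown))
      stop("unknown classifier key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    do.call(behavior_thresholds, cl)
  }

  seeds <- raw$seeds %||% list(simulation = 1L)
  unknown <- setdiff(names(seeds), c("simulation", "network", "stats"))
  if (length(unknown))
    stop("unknown seeds key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(model = model, protocol = proto, network = net,
                 classifier = thresholds, seeds = seeds),
            class = "metaneuron_config")
}

#' Serialise a configuration back to YAML
#'
#' Writing then re-loading reproduces the configuration (round-trip
#' stability).
#'
#' @param config a `metaneuron_config` (from [load_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "metaneuron_config"))
  m <- unclass(config$model)
  m <- c(list(type = if (is_madexp(config$model)) "madexp" else "elif"), m)
  pr <- config$protocol
  plist <- list(duration = pr$duration)
  if (!is.null(pr$segments))
    plist$segments <- lapply(seq_len(nrow(pr$segments)), function(i)
      as.list(pr$segments[i, ]))
  if (!is.null(pr$poisson)) plist$poisson <- pr$poisson
  if (!is.null(pr$alpha_schedule))
    plist$alpha_schedule <- lapply(seq_len(nrow(pr$alpha_schedule)),
                                   function(i)
                                     as.list(pr$alpha_schedule[i, ]))
  out <- list(model = m, protocol = plist)
  if (!is.null(config$network)) {
    nw <- unclass(config$network)
    nw$homeostasis <- lapply(seq_len(nrow(nw$homeostasis)), function(i)
      as.list(nw$homeostasis[i, ]))
    out$network <- nw
  }
  out$classifier <- config$classifier
  out$seeds <- config$seeds
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Shipped preset configurations
#'
#' The package ships frozen presets reproducing the reference scenarios:
#' `fig3_bistable` (bistable eLIF cell with up/down states),
#' `fig4_disease` (eLIF cell whose health decline traverses four stages),
#' `fig5_network_neuron` (the asynchronous-irregular network neuron plus
#' network section and homeostasis table), `s2fig_resonator` (eLIF with
#' `Eu < E0`), and ten mAdExp behavior presets `fig6_RS`, `fig6_AS`,
#' `fig6_IB`, `fig6_RB`, `fig6_TS`, `fig6_DB`, `fig6_DA`, `fig6_IR`,
#' `fig6_ER`, `fig6_IS`.
#'
#' @param name preset name (see [preset_names()]).
#' @return a `metaneuron_config` (see [load_config()]).
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "metaneuron")
  if (path == "")
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  load_config(path)
}

#' @rdname load_preset
#' @export
preset_names <- function() {
  sort(sub("\\.yaml$", "",
           list.files(system.file("extdata", "presets",
                                  package = "metaneuron"),
                      pattern = "\\.yaml$")))
}

#' Reference step currents for the behavior presets
#'
#' Frozen current amplitudes (pA) at which each `fig6_*` preset displays
#' its nominal behavior (`low`, the preset protocol's own amplitude;
#' negative for the post-inhibitory rebound preset) and enters
#' depolarization block (`high`). Together with [load_preset()] and
#' [classify_behavior()] this reproduces the qualitative behavior
#' repertoire: e.g. `fig6_RB` at its low current classifies as `RB`, and
#' every preset classifies as `depol-block` at its high current.
#'
#' @return data.frame with columns `preset`, `label`, `low`, `high`.
#' @examples
#' fig6_reference_currents()
#' @export
fig6_reference_currents <- function() {
  data.frame(
    preset = paste0("fig6_", c("RS", "AS", "IB", "RB", "TS", "DB", "DA",
                               "IR", "ER", "IS")),
    label = c("RS", "AS", "IB", "RB", "TS", "DB", "DA", "IR", "ER", "IS"),
    low = c(300, 300, 350, 210, 230, 265, 130, -170, 22, 250),
    high = c(600, 600, 700, 700, 700, 700, 600, 600, 600, 700),
    stringsAsFactors = FALSE)
}

trace_header <- function(p, seed) {
  c(sprintf("# metaneuron %s trace",
            if (is_madexp(p)) "madexp" else "elif"),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("metaneuron"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("# params: %s",
            paste(sprintf("%s=%g", names(unlist(unclass(p))),
                          unlist(unclass(p))), collapse = " ")))
}

#' Write / read simulation traces and spike files
#'
#' Plain-text tabular output with `#`-prefixed metadata header lines:
#' traces have columns `t`, `V`, `eps`, `w`; spike files one spike time
#' (ms) per line; network spike files two columns `neuron` (1-based id)
#' and `time_ms`.
#'
#' @param result a [simulate_neuron()] result.
#' @param path output path.
#' @return the path, invisibly; readers return a data frame (traces,
#'   network spikes) or numeric vector (spike times).
#' @export
write_trace <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trace_header(result$params, result$seed), con)
  utils::write.table(
    data.frame(t = result$times, V = result$V, eps = result$eps,
               w = result$w),
    con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, comment.char = "#")
}

#' @rdname write_trace
#' @export
write_spikes <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trace_header(result$params, result$seed), con)
  writeLines(format(result$spikes, trim = TRUE), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_spikes <- function(path) {
  x <- readLines(path)
  as.numeric(x[!startsWith(x, "#") & nzchar(x)])
}

#' @rdname write_trace
#' @param trains list of spike-time vectors (network simulation).
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "network_result")) trains <- trains$spike_trains
  d <- data.frame(
    neuron = rep(seq_along(trains), lengths(trains)),
    time_ms = unlist(trains, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metaneuron spike trains (%d neurons)",
                     length(trains)), con)
  utils::write.table(d, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_trace
#' @param n_neurons total neuron count (ids without spikes are kept as
#'   empty trains).
#' @export
read_spike_trains <- function(path, n_neurons = NULL) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  n <- n_neurons %||% max(d$neuron)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- sort(d$time_ms[d$neuron == i])
  out
}
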