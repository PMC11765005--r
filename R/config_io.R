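#' Default run configuration
#'
#' One place for every tunable the CLI commands read.  The values encode
#' the package's reference study conditions: an `so2` world on a 16x16
#' raster with splat sigma 1.5 px, a 200-unit reservoir with leak 0.1 s
#' and spectral radius 0.9, a 25-point constant-latent training grid on
#' the chart `[-0.5, 0.5]` rad, ridge 1e-6, gain grid `10^[-1, 2]`, and
#' a 0.05 Hz slow sinusoid probe path.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    world = list(
      group = "so2",
      rows = 16L, cols = 16L, scale = 1, splat_sigma = 1.5,
      path = list(kind = "sinusoid", amplitude = 0.5, frequency = 0.05,
                  duration = 20, cutoff = 0.5, seed = 1L)),
    agent = list(
      n_hidden = 200L, tau = 0.1, spectral_radius = 0.9, seed = 1L),
    training = list(
      ridge = 1e-6, n_train = 25L, segment = 1.5, burn = 1,
      train_min = -0.5, train_max = 0.5,
      gain_duration = 5, validate_duration = 8),
    simulate = list(dt = 0.01, duration = 20),
    analysis = list(variance_threshold = 0.99, slack = 1L,
                    conserve_tol = 1e-4, membership_tol = 1e-8),
    output = list(dir = "lietrack_out"))
}

# Recursive merge of a user config into defaults; unknown keys error.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key: ",
         paste(c(path, extra[1L]), collapse = "."))
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   c(path, nm))
  defaults
}

#' Load, validate and save run configurations
#'
#' Configurations are YAML.  Unknown keys are rejected by name; missing
#' keys take the [default_config()] values.  `load_config(NULL)` returns
#' the defaults.  Parse-serialize-parse round-trips to an identical
#' structure.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return Nested configuration list with class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    tryCatch(yaml::read_yaml(path),
             error = function(e)
               stop("malformed config ", path, ": ",
                    conditionMessage(e)))
  }
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname load_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run manifest with artifact checksums
#'
#' Records the configuration hash, the seeds and selected gain of a run,
#' and an md5 checksum per artifact file, so that repeated runs of one
#' configuration can be compared byte for byte.
#'
#' @param files Character vector of artifact file paths.
#' @param path Manifest output path (YAML).
#' @param config The `"run_config"` used.
#' @param extra Named list of extra provenance fields (seeds, k_star,
#'   transient time, ...).
#' @return `check_manifest()` returns `TRUE` if every listed file exists
#'   and matches its checksum, else a character vector of mismatches.
#' @export
save_manifest <- function(files, path, config = NULL, extra = list()) {
  sums <- tools::md5sum(files)
  man <- c(list(
    config_hash = if (is.null(config)) NA_character_
                  else config_hash(config),
    artifacts = mapply(function(f, s) list(file = f, md5 = unname(s)),
                       files, sums, SIMPLIFY = FALSE,
                       USE.NAMES = FALSE)),
    extra)
  yaml::write_yaml(man, path)
  invisible(path)
}

#' @rdname save_manifest
#' @export
check_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  bad <- character(0)
  for (a in man$artifacts) {
    if (!file.exists(a$file)) { bad <- c(bad, paste(a$file, "missing")) }
    else if (unname(tools::md5sum(a$file)) != a$md5)
      bad <- c(bad, paste(a$file, "checksum mismatch"))
  }
  if (length(bad)) bad else TRUE
}

#' Delimited-text writers for trajectories and traces
#'
#' Columnar tab-separated text with a header row; numbers are printed
#' with 12 significant digits so that identical runs produce identical
#' bytes.
#'
#' @param run A `"wtne_run"`.
#' @param path Output file.
#' @param thin Keep every `thin`-th sample.
#' @export
write_trajectory <- function(run, path, thin = 1L) {
  traj <- run$trajectory
  keep <- seq(1L, length(traj$times), by = thin)
  m <- cbind(time = traj$times[keep], traj$states[keep, , drop = FALSE])
  colnames(m) <- c("time", sprintf("x%d", seq_len(ncol(m) - 1L)))
  write_num_table(m, path)
}

#' @rdname write_trajectory
#' @export
write_trace <- function(run, path, thin = 1L) {
  tr <- run$trace
  keep <- seq(1L, length(tr$times), by = thin)
  m <- cbind(time = tr$times[keep],
             error_norm = sqrt(rowSums(tr$errors[keep, , drop = FALSE]^2)),
             lyapunov = tr$lyapunov[keep])
  write_num_table(m, path)
}

write_num_table <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.12g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_num_table()` returns a numeric matrix with column names.
#' @export
read_num_table <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
}
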