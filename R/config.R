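# Run configuration: defaults, YAML loading, light logging.

#' Default run configuration
#'
#' All analysis defaults in one place: the four deep gray matter regions,
#' the partial-volume fit options (initialization 1350/850 ms, 10
#' iterations, no early stop, minimum 20 voxels per region), and the
#' statistics options (10000 permutations, Bonferroni correction, seed 1).
#'
#' @return A nested list with elements `regions`, `pve` and `stats`.
#' @export
default_run_config <- function() {
  list(
    regions = c("thalamus", "caudate", "putamen", "pallidum"),
    pve = list(init_mu_gm = 1350, init_mu_wm = 850,
               n_iter = 10, tol = 0, min_voxels = 20),
    stats = list(n_perm = 10000, seed = 1L, correction = "bonferroni")
  )
}

validate_run_config <- function(cfg) {
  if (cfg$pve$init_mu_gm <= cfg$pve$init_mu_wm)
    stop("config: init_mu_gm must exceed init_mu_wm", call. = FALSE)
  if (cfg$pve$n_iter < 1) stop("config: n_iter must be >= 1", call. = FALSE)
  if (cfg$stats$n_perm < 1) stop("config: n_perm must be >= 1", call. = FALSE)
  if (!cfg$stats$correction %in% c("bonferroni", "max_stat_fwe"))
    stop("config: unknown correction '", cfg$stats$correction, "'",
         call. = FALSE)
  cfg
}

#' Read a run configuration from YAML
#'
#' Missing entries fall back to [default_run_config].
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

write_run_log <- function(out_dir, seed, config_path = NULL, timings = NULL) {
  lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("package: t1pve ", as.character(utils::packageVersion("t1pve"))),
    paste0("R: ", R.version.string),
    paste0("seed: ", seed))
  if (!is.null(config_path) && file.exists(config_path))
    lines <- c(lines, paste0("config_md5: ", unname(tools::md5sum(config_path))))
  if (!is.null(timings))
    lines <- c(lines, paste0("elapsed_s: ", round(timings, 2)))
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
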