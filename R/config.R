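#' Packaged run configuration defaults
#'
#' Every pipeline hyperparameter with its shipped default: window 11,
#' contact cutoff 7.5 A, RSA thresholds 0.10/0.40, hidden sizes
#' 500/300/150, sparsity target rho 0.2, weight decay lambda 0.003,
#' sparsity weight beta 3, dropout 0.5.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(task = "sa3",
       window = 11L,
       cutoff_radius = 7.5,
       sequence_separation_min = 3L,
       cap = 14L,
       threshold_bi = 0.10,
       threshold_ie = 0.40,
       hidden_sizes = c(500L, 300L, 150L),
       rho = 0.2,
       beta = 3,
       lam = 0.003,
       dropout_p = 0.5,
       learning_rate = 0.1,
       epochs = 10L,
       batch_size = 32L,
       max_finetune_iters = 200L,
       rng_seed = 1L)
}

#' Resolve a run configuration
#'
#' Precedence: command-line flags > config file > packaged defaults.  The
#' config file is a flat `key: value` YAML-subset document whose keys match
#' the names in [default_run_config()]; `hidden_sizes` may be a list or a
#' comma-separated string.
#'
#' @param flags named list of values supplied on the command line.
#' @param config_file optional path to a config file.
#' @return Named list with class `run_config`.
#' @export
resolve_run_config <- function(flags = list(), config_file = NULL) {
  cfg <- default_run_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    file_cfg <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  flags <- flags[!vapply(flags, is.null, TRUE)]
  unknown <- setdiff(names(flags), names(cfg))
  if (length(unknown))
    stop("unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(flags)] <- flags
  cfg$hidden_sizes <- .parse_int_vector(cfg$hidden_sizes)
  for (k in c("window", "sequence_separation_min", "cap", "epochs",
              "batch_size", "max_finetune_iters", "rng_seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("cutoff_radius", "threshold_bi", "threshold_ie", "rho", "beta",
              "lam", "dropout_p", "learning_rate"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (cfg$window %% 2L == 0L)
    stop("window size must be odd, got ", cfg$window)
  if (!cfg$task %in% c("sa3", "cn15")) stop("task must be sa3 or cn15")
  structure(cfg, class = "run_config")
}

.parse_int_vector <- function(x) {
  if (is.character(x) && length(x) == 1)
    x <- strsplit(x, ",")[[1]]
  out <- as.integer(unlist(x))
  if (length(out) == 0 || anyNA(out))
    stop("hidden_sizes must be positive integers (e.g. \"500,300,150\")")
  out
}

#' Read a two-column max-ASA override table
#'
#' @param path text file with residue letter and max ASA per line.
#' @return Named numeric vector suitable for [solvent_config()].
#' @export
read_max_asa_table <- function(path) {
  df <- utils::read.table(path, col.names = c("residue", "max_asa"),
                          comment.char = "#")
  stats::setNames(as.numeric(df$max_asa), as.character(df$residue))
}
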