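#' Write a state as an extended-XYZ frame
#'
#' One frame per call: the comment line carries `Time=` and a `Properties`
#' declaration (`species:S:1:chain:I:1:pos:R:3`). Monomers are written as
#' species `CHR`, condensins as `CND`.
#'
#' @param state a [chromo_state()].
#' @param file path; use `append = TRUE` to grow a trajectory.
#' @param append append a frame instead of overwriting.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(state, file, append = FALSE) {
  n <- nrow(state$mono_pos); m <- nrow(state$cond_pos)
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(n + m), con)
  writeLines(sprintf('Time=%.10g Properties=species:S:1:chain:I:1:pos:R:3',
                     state$time), con)
  fmt <- function(kind, chain, pos)
    sprintf("%s %d %.8g %.8g %.8g", kind, chain, pos[, 1], pos[, 2], pos[, 3])
  if (n > 0) writeLines(fmt("CHR", state$mono_chain, state$mono_pos), con)
  if (m > 0) writeLines(fmt("CND", state$cond_chain, state$cond_pos), con)
  invisible(file)
}

#' Read extended-XYZ frames written by [write_xyz()]
#'
#' @param file path.
#' @return List of [chromo_state()] objects, one per frame.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    np <- as.integer(lines[i])
    tm <- as.numeric(sub(".*Time=([0-9.eE+-]+).*", "\\1", lines[i + 1L]))
    body <- lines[(i + 2L):(i + 1L + np)]
    parts <- do.call(rbind, strsplit(body, "[[:space:]]+"))
    kind <- parts[, 1]
    chain <- as.integer(parts[, 2])
    pos <- matrix(as.numeric(parts[, 3:5]), ncol = 3)
    is_m <- kind == "CHR"
    frames[[length(frames) + 1L]] <-
      chromo_state(pos[is_m, , drop = FALSE], chain[is_m],
                   cond_pos = pos[!is_m, , drop = FALSE],
                   cond_chain = chain[!is_m], time = tm)
    i <- i + 2L + np
  }
  frames
}

#' Write a topology sidecar table
#'
#' A delimited long-format table with a `record` column: `spring` rows
#' (columns `i`, `j`), `anchor` rows (`i`, `j` = the base-point pair,
#' `loop` = condensin index), and `crossing` rows (`chain`, `loop`, and the
#' bond pair at which the rewire was applied).
#'
#' @param topology a [chromo_topology()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_topology <- function(topology, file) {
  sp <- topology$springs; an <- topology$anchors; cr <- topology$crossings
  df <- rbind(
    data.frame(record = "spring", i = sp[, 1], j = sp[, 2],
               loop = NA_integer_, chain = NA_integer_),
    if (nrow(an) > 0)
      data.frame(record = "anchor", i = an[, 1], j = an[, 2],
                 loop = seq_len(nrow(an)), chain = NA_integer_),
    if (nrow(cr) > 0)
      data.frame(record = "crossing", i = cr$a, j = cr$b,
                 loop = cr$loop, chain = cr$chain))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a topology sidecar written by [write_topology()]
#'
#' @param file path.
#' @return A [chromo_topology()].
#' @export
read_topology <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t")
  sp <- df[df$record == "spring", c("i", "j")]
  an <- df[df$record == "anchor", c("i", "j")]
  cr <- df[df$record == "crossing", , drop = FALSE]
  crossings <- if (nrow(cr) > 0)
    data.frame(chain = cr$chain, loop = cr$loop, a = cr$i, b = cr$j)
  else NULL
  chromo_topology(as.matrix(sp), as.matrix(an), crossings)
}

#' Write an observable series as a delimited table
#'
#' Tab-separated values with a commented header carrying run metadata
#' (parameters, seed, package version) so every table is self-describing.
#'
#' @param series an `observable_series` (or any data frame).
#' @param file path.
#' @param meta named list of metadata written as `# key: value` lines.
#' @return `file`, invisibly.
#' @export
write_series <- function(series, file, meta = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  meta <- c(list(package = paste0("condensim ",
                                  as.character(utils::packageVersion("condensim"))),
                 written = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), meta)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  write.table(as.data.frame(series), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read an observable series written by [write_series()]
#'
#' @param file path.
#' @return Data frame of class `observable_series`; metadata lines are kept
#'   in the `"meta"` attribute.
#' @export
read_series <- function(file) {
  lines <- readLines(file)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  attr(df, "meta") <- sub("^# ", "", meta)
  class(df) <- c("observable_series", "data.frame")
  df
}

#' Read a flat key-value experiment config file
#'
#' The config file is a flat YAML document mirroring [experiment_config()]
#' and [sim_params()] fields, e.g. `mode: segregation`, `N: 500`,
#' `F_cond: 1.0`, `sweep_Delta: [0.5, 2.0]` (grid keys are prefixed
#' `sweep_`).
#'
#' @param path config file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  # keep single-letter keys like N literal (YAML 1.1 would read them as
  # booleans)
  kv <- yaml::read_yaml(path,
                        handlers = list(`bool#yes` = function(x) x,
                                        `bool#no` = function(x) x))
  par_names <- names(formals(sim_params))
  par_args <- kv[intersect(names(kv), par_names)]
  params <- do.call(sim_params, par_args)
  sweep_keys <- grep("^sweep_", names(kv), value = TRUE)
  sweep <- if (length(sweep_keys))
    setNames(kv[sweep_keys], sub("^sweep_", "", sweep_keys))
  else NULL
  cfg_names <- setdiff(names(formals(experiment_config)), c("params", "sweep"))
  cfg_args <- kv[intersect(names(kv), cfg_names)]
  do.call(experiment_config,
          c(cfg_args, list(params = params, sweep = sweep)))
}
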