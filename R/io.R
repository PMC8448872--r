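# Plain-text interchange formats: trajectory files (t,x,y TSV), a cohort
# manifest (id, class, domain, path), speed-series files (one value per line
# with a labelled header), and flat key:value config files.

#' Write / read a trajectory file
#'
#' Tab-separated columns `t`, `x`, `y` with a header row. Labels live in the
#' manifest, not in the trajectory file.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "loco_trajectory"))
  utils::write.table(
    data.frame(t = traj$t, x = traj$x, y = traj$y),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param id,class_label,domain_label Metadata for the returned trajectory
#'   (normally taken from the manifest row).
#' @param path File path to read.
#' @export
read_trajectory <- function(path, id = basename(path), class_label = 0L,
                            domain_label = 0L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("trajectory file must have columns t, x, y: ", path, call. = FALSE)
  trajectory(id, df$t, df$x, df$y, class_label, domain_label)
}

#' Write / read a cohort manifest
#'
#' The manifest is the label store: tab-separated columns `id`, `class`,
#' `domain`, `path`, one row per trajectory file. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param manifest A data.frame with columns id, class, domain, path.
#' @param path Manifest file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("id", "class", "domain", "path") %in% names(manifest)))
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(id = "character", path = "character"))
  if (!all(c("id", "class", "domain", "path") %in% names(df)))
    stop("manifest must have columns id, class, domain, path", call. = FALSE)
  df
}

#' Read every trajectory listed in a manifest
#'
#' @param manifest_path Path to a manifest file.
#' @return A list of [trajectory()] objects.
#' @export
read_cohort <- function(manifest_path) {
  mf <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_trajectory(p, mf$id[i], mf$class[i], mf$domain[i])
  })
}

#' Write / read a speed-series file
#'
#' One value per line; the first line is a header comment of the form
#' `# id=<id> class=<0|1> domain=<0|1> normalized=<0|1>`.
#'
#' @param s A [speed_series()].
#' @param path File path.
#' @export
write_speed_series <- function(s, path) {
  stopifnot(inherits(s, "speed_series"))
  hdr <- sprintf("# id=%s class=%d domain=%d normalized=%d",
                 s$id, s$class_label, s$domain_label, as.integer(s$normalized))
  writeLines(c(hdr, format(s$values, digits = 17, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}

#' @rdname write_speed_series
#' @export
read_speed_series <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# "))
    stop("missing speed-series header: ", path, call. = FALSE)
  kv <- parse_kv_pairs(sub("^# ", "", lines[1L]))
  speed_series(kv[["id"]], as.numeric(lines[-1L]),
               as.integer(kv[["class"]]), as.integer(kv[["domain"]]),
               normalized = kv[["normalized"]] == "1")
}

parse_kv_pairs <- function(line) {
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Read a flat key:value configuration file
#'
#' One `key: value` (or `key = value`) pair per line; `#` starts a comment.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}
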