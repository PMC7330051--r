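#' Write a trajectory to a text extended-XYZ-style file
#'
#' One block per frame: a sphere-count line, a comment line
#' `time=<t> box=<L> n_twitchers=<N> columns=...`, then one row per sphere
#' with wrapped and unwrapped positions, twitcher id, sphere index within
#' the twitcher (1 = tail, 4 = head), phase letter (R/E/T) and the wrapped
#' pilus anchor (NA unless retracting). Positions are printed with 17
#' significant digits so the write/read round trip is lossless.
#'
#' @param sim a `twitch_sim` run with `keep_spheres = TRUE`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_traj <- function(sim, path) {
  if (is.null(sim$spheres))
    stop("trajectory has no per-sphere data; rerun with keep_spheres = TRUE",
         call. = FALSE)
  F <- n_frames(sim)
  N <- sim$n_twitchers
  ns <- 4 * N
  tw <- rep(seq_len(N), each = 4)
  sp <- rep(1:4, N)
  con <- file(path, "w")
  on.exit(close(con))
  g <- function(x) sprintf("%.17g", x)
  for (f in seq_len(F)) {
    writeLines(as.character(ns), con)
    writeLines(sprintf(
      "time=%s box=%s n_twitchers=%d columns=x y xu yu twitcher sphere phase ax ay",
      g(sim$time[f]), g(sim$box_L), N), con)
    ph <- phase_levels[sim$phase[f, tw] + 1L]
    anc <- sim$spheres$anchor[f, , , drop = FALSE]
    rows <- paste(g(sim$spheres$wrapped[f, , 1]),
                  g(sim$spheres$wrapped[f, , 2]),
                  g(sim$spheres$unwrapped[f, , 1]),
                  g(sim$spheres$unwrapped[f, , 2]),
                  tw, sp, ph,
                  ifelse(is.na(anc[1, tw, 1]), "NA", g(anc[1, tw, 1])),
                  ifelse(is.na(anc[1, tw, 2]), "NA", g(anc[1, tw, 2])))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Parses the format written by [write_traj()] and rebuilds a
#' [twitch_traj()] with per-twitcher kinematics (centre of mass, per-frame
#' velocity, polar orientation) derived from the sphere positions exactly
#' as the simulator derives them, so analyses give identical results
#' in-memory and from file.
#'
#' @param path trajectory file.
#' @param params optional [twitch_params()] attached to the result.
#' @return A `twitch_traj` (with `$spheres`); an empty file yields a
#'   trajectory with 0 frames.
#' @export
read_traj <- function(path, params = NULL) {
  lines <- readLines(path)
  # drop trailing blank lines
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) {
    return(twitch_traj(time = numeric(0),
                       com = array(0, c(0, 0, 2)), box_L = NA_real_,
                       params = params))
  }
  ns <- suppressWarnings(as.integer(lines[1]))
  if (is.na(ns) || ns <= 0 || ns %% 4 != 0)
    stop("malformed trajectory: bad sphere count at line 1", call. = FALSE)
  block <- ns + 2L
  if (length(lines) %% block != 0)
    stop("truncated trajectory: frame ",
         length(lines) %/% block + 1L, " is incomplete", call. = FALSE)
  F <- length(lines) %/% block
  N <- ns %/% 4L
  time <- numeric(F)
  box_L <- NA_real_
  sphw <- array(NA_real_, c(F, ns, 2))
  sphu <- array(NA_real_, c(F, ns, 2))
  phase <- matrix(NA_integer_, F, N)
  anchor <- array(NA_real_, c(F, N, 2))
  for (f in seq_len(F)) {
    o <- (f - 1L) * block
    cnt <- suppressWarnings(as.integer(lines[o + 1L]))
    if (is.na(cnt) || cnt != ns)
      stop("malformed trajectory: bad count line for frame ", f,
           " (line ", o + 1L, ")", call. = FALSE)
    hdr <- lines[o + 2L]
    kv <- regmatches(hdr, gregexpr("[a-zA-Z_]+=[^ ]+", hdr))[[1]]
    kvs <- strsplit(kv, "=", fixed = TRUE)
    vals <- setNames(vapply(kvs, `[`, "", 2), vapply(kvs, `[`, "", 1))
    time[f] <- as.numeric(vals[["time"]])
    box_L <- as.numeric(vals[["box"]])
    body <- lines[o + 2L + seq_len(ns)]
    m <- utils::read.table(text = body, colClasses = c(rep("numeric", 4),
                           "integer", "integer", "character",
                           "numeric", "numeric"))
    if (nrow(m) != ns || ncol(m) != 9)
      stop("malformed trajectory: bad sphere rows in frame ", f,
           call. = FALSE)
    sphw[f, , 1] <- m[[1]]; sphw[f, , 2] <- m[[2]]
    sphu[f, , 1] <- m[[3]]; sphu[f, , 2] <- m[[4]]
    phf <- match(m[[7]], phase_levels) - 1L
    if (any(is.na(phf)))
      stop("malformed trajectory: unknown phase code in frame ", f,
           call. = FALSE)
    phase[f, ] <- phf[4 * seq_len(N)]
    anchor[f, , 1] <- m[[8]][4 * seq_len(N)]
    anchor[f, , 2] <- m[[9]][4 * seq_len(N)]
  }
  if (F > 1 && any(diff(time) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  # per-twitcher kinematics, as the simulator derives them
  com <- array(NA_real_, c(F, N, 2))
  polar <- array(NA_real_, c(F, N, 2))
  for (n in seq_len(N)) {
    idx <- 4L * (n - 1L) + 1:4
    com[, n, 1] <- rowMeans(sphu[, idx, 1, drop = FALSE], dims = 1)
    com[, n, 2] <- rowMeans(sphu[, idx, 2, drop = FALSE], dims = 1)
    px <- sphu[, idx[4], 1] - sphu[, idx[1], 1]
    py <- sphu[, idx[4], 2] - sphu[, idx[1], 2]
    pr <- sqrt(px^2 + py^2)
    polar[, n, 1] <- px / pr
    polar[, n, 2] <- py / pr
  }
  vel <- array(NA_real_, c(F, N, 2))
  if (F > 1) {
    dtf <- time[2] - time[1]
    vel[-1, , ] <- (com[-1, , , drop = FALSE] -
                    com[-F, , , drop = FALSE]) / dtf
  }
  phase_start <- phase
  if (F > 1) phase_start[-1, ] <- phase[-F, ]
  out <- twitch_traj(time = time, com = com, com_wrapped = com %% box_L,
                     vel = vel, phase = phase, phase_start = phase_start,
                     polar = polar, box_L = box_L, params = params)
  out$spheres <- list(wrapped = sphw, unwrapped = sphu, anchor = anchor)
  out
}

#' Write or read an observable table
#'
#' CSV with `# key=value` comment header lines carrying the run metadata
#' (statistic name, coverage, seed, fit ranges, ...).
#'
#' @param x a data frame (any of the package's curve objects).
#' @param path output file.
#' @param meta named list or vector of metadata values.
#' @return Invisibly, `path`.
#' @export
write_observable <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, format(meta[[nm]])), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observable
#' @return For `read_observable`, the data frame with a `meta` attribute.
#' @export
read_observable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    parts <- strsplit(kv, "=", fixed = TRUE)
    meta <- setNames(lapply(parts, function(p) {
      v <- paste(p[-1], collapse = "=")
      nv <- suppressWarnings(as.numeric(v))
      if (is.na(nv)) v else nv
    }), vapply(parts, `[`, "", 1))
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write or read a simulation configuration
#'
#' Round-trips [twitch_params()] through a YAML file whose keys mirror the
#' parameter names.
#'
#' @param params a [twitch_params()] object.
#' @param path file path.
#' @return Invisibly `path`; for `read_config`, the `twitch_params`.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  known <- names(formals(twitch_params))
  do.call(twitch_params, v[intersect(names(v), known)])
}
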