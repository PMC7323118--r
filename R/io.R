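#' Read a tabulated bending-energy profile from a text file
#'
#' Two-column whitespace- or comma-separated text: column 1 = bend angle,
#' column 2 = energy in kT.  A non-numeric first row is treated as a header.
#' Angles must be strictly increasing; at least 4 rows are required.
#'
#' @param path file path.
#' @param degrees if `TRUE`, the angle column is in degrees and is converted
#'   to radians on input.
#' @return a tabulated [bending_profile][tabulated_profile].
#' @export
read_profile_table <- function(path, degrees = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_row <- function(s) suppressWarnings(
    as.numeric(strsplit(s, "[,[:space:]]+")[[1]]))
  rows <- lapply(lines, parse_row)
  if (length(rows) > 0 && anyNA(rows[[1]])) rows <- rows[-1]   # header
  if (length(rows) < 4L)
    stop("profile table needs at least 4 data rows: ", path, call. = FALSE)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < 2L || anyNA(r[1:2]))
      stop("non-numeric cell in profile table at data row ", i, call. = FALSE)
  }
  m <- do.call(rbind, lapply(rows, function(r) r[1:2]))
  theta <- m[, 1]
  if (degrees) theta <- theta * pi / 180
  bad <- which(diff(theta) <= 0)
  if (length(bad) > 0)
    stop("angles not strictly increasing at data row ", bad[1] + 1L,
         call. = FALSE)
  tabulated_profile(theta, m[, 2])
}

#' Write a bending-energy profile to a two-column text file
#'
#' Emits the same format [read_profile_table()] reads: a `# angle_rad
#' energy_kT` header comment followed by two whitespace-separated columns.
#'
#' @param profile a `bending_profile`.
#' @param path output file.
#' @param theta evaluation knots, radians; defaults to the tabulated knots
#'   or 101 points over the domain for analytic kinds.
#' @param degrees write angles in degrees.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path, theta = NULL, degrees = FALSE) {
  if (is.null(theta)) {
    theta <- if (inherits(profile, "tabulated_profile")) profile$theta
             else seq(profile$domain[1], profile$domain[2], length.out = 101)
  }
  e <- profile_energy(profile, theta)
  ang <- if (degrees) theta * 180 / pi else theta
  hdr <- sprintf("# %s energy_kT", if (degrees) "angle_deg" else "angle_rad")
  writeLines(c(hdr, sprintf("%.12g %.12g", ang, e)), path)
  invisible(path)
}

#' Write a multi-frame XYZ trajectory
#'
#' Standard XYZ: atom-count line, comment line (frame index and energy when
#' available), then `element x y z` in Angstrom, frames concatenated.
#'
#' @param frames a single coordinate matrix, a list of `N x 3` matrices, or
#'   a `loop_ensemble`/`confined_ensemble` with stored coordinates.
#' @param path output file.
#' @param element element tag written for every bead.
#' @param energies optional per-frame energies for the comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, element = "C", energies = NULL) {
  if (inherits(frames, c("loop_ensemble", "confined_ensemble"))) {
    if (is.null(frames$coords))
      stop("ensemble has no stored coordinates; rerun with record_coords = TRUE",
           call. = FALSE)
    if (is.null(energies)) energies <- frames$bend_energy
    frames <- frames$coords
  }
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("no frames to write", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    cmt <- sprintf("frame %d", f)
    if (!is.null(energies) && length(energies) >= f)
      cmt <- sprintf("%s energy_kT %.6f", cmt, energies[f])
    writeLines(c(as.character(nrow(m)), cmt), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", element, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file path.
#' @return list of `N x 3` coordinate matrices.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  frames
}

#' Generate synthetic fixtures with known ground truth
#'
#' Deterministic-from-seed synthetic inputs for testing every analysis path
#' without external data:
#' \describe{
#'   \item{`"convex-profile"`}{a tabulated harmonic profile (no hull).}
#'   \item{`"nonconvex-profile"`}{a random non-convex quartic, tabulated on
#'     a fine grid; the returned `truth` records the generator's quartic
#'     coefficients and its brute-force hull endpoints.}
#'   \item{`"noisy-jfactor"`}{(L, j) pairs drawn from the closed-form
#'     j-factor with a known prefactor `k` and multiplicative lognormal
#'     noise.}
#'   \item{`"toy-loop"`}{a regular ring geometry as an XYZ file.}
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param k,sdlog,n_points parameters of the noisy j-factor fixture.
#' @return list with `files` (paths written) and `truth` (generator ground
#'   truth).
#' @export
make_fixtures <- function(kind = c("convex-profile", "nonconvex-profile",
                                   "noisy-jfactor", "toy-loop"),
                          seed = 1L, dir = tempdir(),
                          k = 0.07, sdlog = 0.1, n_points = 50L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (kind == "convex-profile") {
    p <- harmonic_profile(100 + 100 * runif(1))
    f <- file.path(dir, sprintf("convex_profile_seed%d.tsv", seed))
    write_profile_table(p, f, theta = seq(0, 1, length.out = 201))
    return(list(files = f, truth = list(Lp = p$Lp, hull = NULL)))
  }
  if (kind == "nonconvex-profile") {
    # c2 th^2 + c3 th^3 + c4 th^4 is non-convex iff 9 c3^2 > 32 c2 c4 with
    # c2, c4 > 0 and c3 < 0; rejection-sample until the hull sits inside
    # the tabulation window.
    repeat {
      c2 <- runif(1, 50, 400)
      c3 <- -runif(1, 2.5, 4.5) * c2
      c4 <- runif(1, 1.1, 2.2) * abs(c3)
      if (9 * c3^2 <= 32 * c2 * c4) next
      q <- quartic_profile(c2, c3, c4, domain = c(0, 1.2))
      h <- tryCatch(find_double_tangent(q), error = function(e) NULL)
      if (!is.null(h) && h$theta_b < 1.1) break
    }
    f <- file.path(dir, sprintf("nonconvex_profile_seed%d.tsv", seed))
    write_profile_table(q, f, theta = seq(0, 1.2, length.out = 601))
    return(list(files = f,
                truth = list(c2 = c2, c3 = c3, c4 = c4,
                             theta_a = h$theta_a, theta_b = h$theta_b)))
  }
  if (kind == "noisy-jfactor") {
    L <- round(seq(60, 200, length.out = n_points))
    j <- jfactor(L, "ech", Lp = 150, theta_a = 2.2 * pi / 180, k = k) *
      stats::rlnorm(n_points, 0, sdlog)
    f <- file.path(dir, sprintf("jfactor_seed%d.tsv", seed))
    writeLines(c("# L_bp j_relative", sprintf("%d %.8e", L, j)), f)
    return(list(files = f,
                truth = list(k = k, Lp = 150, theta_a = 2.2 * pi / 180,
                             model = "ech")))
  }
  # toy-loop
  N <- sample(12:60, 1)
  ring <- build_regular_loop(N)
  f <- file.path(dir, sprintf("toy_loop_seed%d.xyz", seed))
  write_xyz(ring$coords, f)
  list(files = f, truth = list(N = N, b = ring$b))
}

#' Plain-text run configuration files
#'
#' Serialises a flat named list of run parameters to `key = value` lines and
#' back.  Numbers, logicals and strings round-trip identically; every CLI
#' run logs its resolved configuration in this form.
#'
#' @param config named list of scalar parameters.
#' @param path file path.
#' @return `read_run_config()` returns the named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else sprintf("%.17g", v)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) stop("malformed config line", call. = FALSE)
    val <- m[3]
    out[[m[2]]] <-
      if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else if (grepl("^[-+0-9.eE]+$", val) &&
               !is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
      else val
  }
  out
}
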