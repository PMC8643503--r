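#' Acquisition protocol for the SPGR triplet and multi-shell diffusion scan
#'
#' Bundles the settings needed to forward-simulate and to invert the imaging
#' model: flip angle and repetition time for each of the PD-weighted,
#' T1-weighted and MT-weighted spoiled gradient echo (SPGR) acquisitions,
#' plus the diffusion gradient table and the fixed model diffusivities.
#'
#' Flip angles are taken in degrees at the interface and stored in radians
#' internally; all downstream maths uses the radian values.
#'
#' @param spgr Named list with components `pdw`, `t1w`, `mtw`, each a list
#'   `list(flip_deg =, tr_s =)`; flip angle in degrees in (0, 90], TR in
#'   seconds.
#' @param bvals Numeric vector of b-values in s/mm^2 (>= 0; zeros mark the
#'   non-diffusion-weighted volumes).
#' @param bvecs 3 x n matrix of gradient directions (columns). Directions of
#'   b > 0 entries must be unit vectors; b = 0 directions are arbitrary.
#' @param d_parallel Intrinsic parallel diffusivity of the neurite
#'   compartment, mm^2/s.
#' @param d_iso Isotropic (free-water) diffusivity, mm^2/s.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(spgr, bvals, bvecs,
                                 d_parallel = 1.7e-3, d_iso = 3.0e-3) {
  for (nm in c("pdw", "t1w", "mtw")) {
    s <- spgr[[nm]]
    if (is.null(s) || is.null(s$flip_deg) || is.null(s$tr_s)) {
      stop("spgr$", nm, " must provide flip_deg and tr_s")
    }
    if (s$flip_deg <= 0 || s$flip_deg > 90) {
      stop("spgr$", nm, " flip angle must be in (0, 90] degrees")
    }
    if (s$tr_s <= 0) stop("spgr$", nm, " TR must be positive")
  }
  bvals <- as.numeric(bvals)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x n matrix (columns = directions)")
  if (ncol(bvecs) != length(bvals)) {
    stop("count mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " directions")
  }
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & abs(nrm - 1) > 1e-6)) {
    stop("diffusion-weighted directions must be unit vectors")
  }
  spgr_rad <- lapply(spgr[c("pdw", "t1w", "mtw")], function(s) {
    list(flip_deg = s$flip_deg, flip_rad = s$flip_deg * pi / 180, tr_s = s$tr_s)
  })
  structure(
    list(spgr = spgr_rad, bvals = bvals, bvecs = bvecs,
         d_parallel = d_parallel, d_iso = d_iso),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("<acquisition_protocol>\n")
  for (nm in c("pdw", "t1w", "mtw")) {
    s <- x$spgr[[nm]]
    cat(sprintf("  %s: flip %.1f deg, TR %.1f ms\n", nm, s$flip_deg, 1000 * s$tr_s))
  }
  shells <- table(round(x$bvals))
  cat("  diffusion:", paste(sprintf("b=%s (n=%d)", names(shells), as.integer(shells)),
                            collapse = ", "), "\n")
  cat(sprintf("  d_parallel %.2e, d_iso %.2e mm^2/s\n", x$d_parallel, x$d_iso))
  invisible(x)
}

## Deterministic, roughly uniform directions on the unit sphere
## (spherical Fibonacci point set, restricted to one hemisphere as is
## conventional for diffusion gradient tables).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n          # upper hemisphere: z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Default acquisition protocol
#'
#' A conventional multi-parameter-mapping style SPGR triplet (PDw 6 deg /
#' 25 ms, T1w 21 deg / 11 ms, MTw 6 deg / 25 ms) and a two-shell diffusion
#' scheme (b = 700 and 2000 s/mm^2, 32 directions each, plus interleaved
#' b = 0 volumes).
#'
#' @param bshells Numeric vector of non-zero shell b-values, s/mm^2.
#' @param n_dir Directions per non-zero shell.
#' @param n_b0 Number of b = 0 volumes.
#' @inheritParams acquisition_protocol
#' @return An `acquisition_protocol`.
#' @export
default_protocol <- function(bshells = c(700, 2000), n_dir = 32, n_b0 = 4,
                             d_parallel = 1.7e-3, d_iso = 3.0e-3) {
  dirs <- fibonacci_directions(n_dir)
  bvals <- c(rep(0, n_b0), rep(bshells, each = n_dir))
  bvecs <- cbind(matrix(0, 3, n_b0),
                 do.call(cbind, replicate(length(bshells), dirs, simplify = FALSE)))
  acquisition_protocol(
    spgr = list(pdw = list(flip_deg = 6,  tr_s = 0.025),
                t1w = list(flip_deg = 21, tr_s = 0.011),
                mtw = list(flip_deg = 6,  tr_s = 0.025)),
    bvals = bvals, bvecs = bvecs,
    d_parallel = d_parallel, d_iso = d_iso
  )
}

#' Write / read an acquisition protocol as JSON
#'
#' The JSON carries the SPGR settings (degrees / seconds), the gradient
#' table and the model diffusivities. A file without a diffusion section
#' reads back with a single b = 0 placeholder entry, which is sufficient
#' for the relaxometry tools.
#'
#' @param protocol An `acquisition_protocol`.
#' @param path JSON path.
#' @return `write_protocol_json()` returns `path` invisibly;
#'   `read_protocol_json()` an `acquisition_protocol`.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(list(
    spgr = lapply(protocol$spgr, function(s) {
      list(flip_deg = s$flip_deg, tr_s = s$tr_s)
    }),
    bvals = protocol$bvals,
    bvecs = protocol$bvecs,
    d_parallel = protocol$d_parallel,
    d_iso = protocol$d_iso
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$bvals)) {
    cfg$bvals <- 0
    cfg$bvecs <- matrix(0, 3, 1)
  }
  acquisition_protocol(cfg$spgr, cfg$bvals, as.matrix(cfg$bvecs),
                       d_parallel = cfg$d_parallel %||% 1.7e-3,
                       d_iso = cfg$d_iso %||% 3.0e-3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an FSL-dialect gradient table
#'
#' `write_bval_bvec()` writes `<prefix>.bval` (one whitespace-separated row
#' of b-values) and `<prefix>.bvec` (three rows: x, y, z components).
#' `read_bval_bvec()` reads the pair back.
#'
#' @param protocol An `acquisition_protocol`.
#' @param prefix Path prefix for the two text files.
#' @return `write_bval_bvec()` returns the two paths invisibly;
#'   `read_bval_bvec()` returns `list(bvals =, bvecs =)`.
#' @export
write_bval_bvec <- function(protocol, prefix) {
  bval_path <- paste0(prefix, ".bval")
  bvec_path <- paste0(prefix, ".bvec")
  writeLines(paste(format(protocol$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(protocol$bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10, scientific = FALSE), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvec_rows <- readLines(paste0(prefix, ".bvec"))
  bvec_rows <- bvec_rows[nzchar(trimws(bvec_rows))]
  if (length(bvec_rows) != 3L) stop("bvec file must have exactly 3 rows")
  bvecs <- do.call(rbind, lapply(bvec_rows, function(r) scan(text = r, quiet = TRUE)))
  if (ncol(bvecs) != length(bvals)) {
    stop("bval/bvec count mismatch: ", length(bvals), " vs ", ncol(bvecs))
  }
  list(bvals = bvals, bvecs = bvecs)
}
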