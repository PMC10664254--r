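# Deterministic synthetic point clouds and toy structure files, so every
# codec property is testable without downloading real structures. The
# generator is seeded R Mersenne-Twister (the session RNG state is saved
# and restored around each call).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic atomic point cloud
#'
#' Three generation modes emulate the regimes the codec must handle:
#' \describe{
#'   \item{uniform_ball}{points uniform in the ball of radius `r_max` —
#'     a featureless cloud with the widest spread of radii.}
#'   \item{chain_walk}{a persistent random walk with 1.5 Angstrom steps
#'     (roughly a bond length), reflected toward the origin at the ball
#'     boundary — protein-like local density, many near-equal radii.}
#'   \item{duplicate_heavy}{a uniform cloud in which about 20 percent of
#'     the points are exact copies of earlier points — an adversarial case
#'     that forces pointer records and overflow images.}
#' }
#'
#' @param n number of points (>= 1).
#' @param r_max ball radius in Angstrom.
#' @param mode one of `"uniform_ball"`, `"chain_walk"`,
#'   `"duplicate_heavy"`.
#' @param seed integer seed; the same spec always yields the same cloud.
#' @return numeric matrix (n x 3) of Cartesian coordinates.
#' @export
#' @examples
#' cloud <- generate_cloud(100, r_max = 25, mode = "chain_walk", seed = 1)
generate_cloud <- function(n, r_max = 50,
                           mode = c("uniform_ball", "chain_walk",
                                    "duplicate_heavy"),
                           seed = 1) {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1")
  if (r_max <= 0) stop("r_max must be positive")
  with_seed(seed, switch(mode,
    uniform_ball = cloud_uniform_ball(n, r_max),
    chain_walk = cloud_chain_walk(n, r_max),
    duplicate_heavy = cloud_duplicate_heavy(n, r_max)))
}

cloud_uniform_ball <- function(n, r_max) {
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
  r <- r_max * stats::runif(n)^(1 / 3)
  dir * r
}

cloud_chain_walk <- function(n, r_max) {
  out <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  heading <- c(1, 0, 0)
  for (i in seq_len(n)) {
    heading <- 0.7 * heading + stats::rnorm(3)
    heading <- heading / max(sqrt(sum(heading^2)), 1e-12)
    step <- pos + 1.5 * heading
    if (sqrt(sum(step^2)) > r_max) {  # turn back inside the ball
      heading <- -step / sqrt(sum(step^2))
      step <- pos + 1.5 * heading
    }
    pos <- step
    out[i, ] <- pos
  }
  out
}

cloud_duplicate_heavy <- function(n, r_max) {
  out <- cloud_uniform_ball(n, r_max)
  if (n >= 2L) {
    k <- floor(0.2 * n)
    idx <- sample(2:n, k, replace = FALSE)
    for (i in sort(idx))
      out[i, ] <- out[sample.int(i - 1L, 1L), ]
  }
  out
}

#' Render a point cloud as a minimal PDB file
#'
#' One ATOM record per point (alpha carbons of a single poly-glycine
#' chain), terminated by an END record; [read_structure()] inverts it
#' exactly.
#'
#' @param points numeric matrix (n x 3); every coordinate must fit the
#'   fixed 8.3 PDB field, i.e. lie in (-1000, 10000).
#' @return raw vector of PDB file bytes.
#' @export
make_toy_pdb <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  if (n == 0L) stop("cannot render an empty point list")
  if (any(points <= -1000 | points >= 10000))
    stop("coordinates overflow the 8-character PDB field")
  serial <- (seq_len(n) - 1L) %% 99999L + 1L
  resseq <- (seq_len(n) - 1L) %% 9999L + 1L
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C\n",
    serial, resseq, points[, 1], points[, 2], points[, 3])
  charToRaw(paste0(paste(lines, collapse = ""), "END\n"))
}
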