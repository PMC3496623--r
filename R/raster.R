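#' Binary spike raster with an explicit past convention
#'
#' A raster records which neurons fire at each integer time.  The
#' in-memory object holds a finite \code{N x T} 0/1 window whose columns
#' are the consecutive integer times \code{t0, ..., t0 + T - 1}; the
#' \code{past_padding} field states the assumed spiking state at every
#' time before \code{t0}: \code{"zeros"} (no neuron ever fired before
#' the window, the lowest-conductance past) or \code{"ones"} (every
#' neuron fired at every earlier integer, the highest-conductance past).
#' The padding stands in for the infinite past on which all
#' history-dependent quantities of the model are defined; downstream
#' integrals truncate that past at a horizon where their tail bound
#' falls below tolerance.
#'
#' @param omega \code{N x T} matrix with entries 0/1 (columns = time).
#' @param t0 integer time of the first column.
#' @param past_padding \code{"zeros"} or \code{"ones"}.
#' @return an object of class \code{"gif_raster"}.
#' @export
gif_raster <- function(omega, t0 = 1L, past_padding = c("zeros", "ones")) {
  past_padding <- match.arg(past_padding)
  omega <- as.matrix(omega)
  storage.mode(omega) <- "integer"
  if (!all(omega %in% c(0L, 1L)))
    stop("raster entries must be exactly 0 or 1")
  structure(list(omega = omega, t0 = as.integer(t0),
                 past_padding = past_padding),
            class = "gif_raster")
}

#' Raster fixtures
#'
#' Builds the reference rasters used throughout the analysis: the
#' all-zero raster (no neuron ever fires; zeros padding), the all-one
#' raster (every neuron fires at every time; ones padding), or a seeded
#' i.i.d. Bernoulli raster with zeros padding.
#'
#' @param kind \code{"omega0"}, \code{"omega1"} or \code{"random"}.
#' @param N,T dimensions (neurons x time steps), both >= 1.
#' @param t0 time of the first column.
#' @param p firing probability for \code{kind = "random"}.
#' @param seed integer seed for \code{kind = "random"}.
#' @return a [gif_raster()] object.
#' @export
raster_fixture <- function(kind = c("omega0", "omega1", "random"),
                           N, T, t0 = 1L, p = 0.3, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(N >= 1, T >= 1)
  switch(kind,
    omega0 = gif_raster(matrix(0L, N, T), t0, "zeros"),
    omega1 = gif_raster(matrix(1L, N, T), t0, "ones"),
    random = .with_seed(seed, gif_raster(
      matrix(stats::rbinom(N * T, 1L, p), N, T), t0, "zeros")))
}

.raster_t_end <- function(raster) raster$t0 + ncol(raster$omega) - 1L

# 0/1 value of omega_k(n) under the padding convention; n vectorized.
.omega_at <- function(raster, k, n) {
  out <- integer(length(n))
  before <- n < raster$t0
  if (raster$past_padding == "ones") out[before] <- 1L
  inw <- !before & n <= .raster_t_end(raster)
  if (any(inw)) out[inw] <- raster$omega[k, n[inw] - raster$t0 + 1L]
  out
}

#' Spike times of one neuron within a time range
#'
#' Integer times \code{n} in \code{[from, to]} with
#' \code{omega_k(n) = 1}, under the raster's padding convention (with
#' ones padding every integer before the window counts as a spike).
#'
#' @param raster a [gif_raster()] object.
#' @param j neuron index.
#' @param from,to closed integer range to scan.
#' @return increasing integer vector of spike times.
#' @export
spike_times <- function(raster, j, from, to) {
  from <- ceiling(from); to <- floor(to)
  if (to < from) return(integer(0))
  s <- integer(0)
  if (raster$past_padding == "ones" && from < raster$t0)
    s <- seq.int(from, min(to, raster$t0 - 1L))
  w_from <- max(from, raster$t0)
  w_to <- min(to, .raster_t_end(raster))
  if (w_to >= w_from) {
    cols <- seq.int(w_from, w_to) - raster$t0 + 1L
    s <- c(s, (w_from:w_to)[raster$omega[j, cols] == 1L])
  }
  s
}

#' Last reset time of a neuron before a (real) time
#'
#' Returns the most recent integer time \code{n <= floor(t)} at which
#' neuron \code{k} fired (a recorded spike resets the membrane potential
#' at its integer time), or \code{-Inf} when the neuron never fired
#' under the raster's padding convention.  Floor follows the integer
#' convention \code{floor(-1.2) = -2}.
#'
#' @param raster a [gif_raster()] object.
#' @param k neuron index.
#' @param t real time.
#' @return an integer time, or \code{-Inf}.
#' @export
last_reset <- function(raster, k, t) {
  n_max <- floor(t)
  w_hi <- min(n_max, .raster_t_end(raster))
  if (w_hi >= raster$t0) {
    cols <- seq.int(raster$t0, w_hi) - raster$t0 + 1L
    hits <- which(raster$omega[k, cols] == 1L)
    if (length(hits)) return(raster$t0 + hits[length(hits)] - 1L)
  }
  if (raster$past_padding == "ones") return(min(n_max, raster$t0 - 1L))
  -Inf
}

#' Depth of agreement of two rasters at a time
#'
#' Largest \code{m >= 0} such that the two rasters carry identical
#' spiking patterns at every time in \code{n - m, ..., n}; comparison
#' extends into the padding region and is capped at the combined
#' window-plus-padding extent (the cap is returned when the rasters
#' agree everywhere, including their padding conventions).  Returns
#' \code{-1} when the patterns already differ at time \code{n}.
#'
#' @param r1,r2 [gif_raster()] objects with equal neuron counts.
#' @param n integer time covered by both windows.
#' @return integer agreement depth (or the cap).
#' @export
agree_depth <- function(r1, r2, n) {
  stopifnot(nrow(r1$omega) == nrow(r2$omega))
  N <- nrow(r1$omega)
  lo <- min(r1$t0, r2$t0)
  cap <- n - lo + 1L  # depths 0 .. cap-1 are informative; cap = full agreement
  for (m in 0:(cap - 1L)) {
    r <- n - m
    p1 <- vapply(seq_len(N), function(k) .omega_at(r1, k, r), integer(1))
    p2 <- vapply(seq_len(N), function(k) .omega_at(r2, k, r), integer(1))
    if (!all(p1 == p2)) return(m - 1L)
  }
  if (r1$past_padding == r2$past_padding) cap else cap - 1L
}

#' @export
print.gif_raster <- function(x, ...) {
  Tn <- ncol(x$omega)
  cat(sprintf("gIF raster: %d neurons x %d steps, times %d..%d, past = %s\n",
              nrow(x$omega), Tn, x$t0, .raster_t_end(x), x$past_padding))
  cat(sprintf("  firing rate: %.3f spikes/neuron/step\n", mean(x$omega)))
  invisible(x)
}

#' Write / read a raster as plain text
#'
#' Format: a header line \code{# gifnet-raster N=<N> t0=<t0>
#' padding=<zeros|ones>} followed by one line per time step of \code{N}
#' space-separated 0/1 values.
#'
#' @param raster a [gif_raster()] object.
#' @param path file path.
#' @return \code{write_raster} returns \code{path} invisibly;
#'   \code{read_raster} returns the reconstructed [gif_raster()].
#' @export
write_raster <- function(raster, path) {
  header <- sprintf("# gifnet-raster N=%d t0=%d padding=%s",
                    nrow(raster$omega), raster$t0, raster$past_padding)
  lines <- apply(raster$omega, 2L, paste, collapse = " ")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# gifnet-raster ", lines[1]))
    stop("not a gifnet raster file: missing header")
  h <- lines[1]
  get_field <- function(name) sub(sprintf(".*%s=([^ ]+).*", name), "\\1", h)
  N <- as.integer(get_field("N"))
  t0 <- as.integer(get_field("t0"))
  padding <- get_field("padding")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  om <- vapply(strsplit(trimws(body), "[[:space:]]+"),
               function(x) as.integer(x), integer(N))
  om <- matrix(om, nrow = N)
  gif_raster(om, t0, padding)
}

# append one spiking pattern (length-N 0/1) at the next time step
.raster_append <- function(raster, pattern) {
  raster$omega <- cbind(raster$omega, as.integer(pattern))
  raster
}
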