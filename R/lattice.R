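# 2D stochastic model of glycan insertion at the leading edge (LE). The
# cell circumference is discretized into M periodic columns; glycan hoops
# stack as rows from the founding (septal) row upward. The height profile
# is the contiguous membrane-LE front per column: insertion-degradation
# complexes (IDCs) ride the membrane LE and always insert at the local
# front site, moving processively around the circumference. The old-wall
# template carries independent gaps (density f0) crossed with probability
# ppro; a strand terminating at a gap leaves an exposed-end defect that
# marks the column, and any later attempt there requires repair
# (probability prep). Idle IDCs bind a uniformly random LE column and
# initiate polymerization from the glycan end there with probability prep.

#' Configuration of the leading-edge lattice model
#'
#' @param M number of circumference segments (default 1570).
#' @param H_target stop height in glycan rows (default 500); the run stops
#'   once the mean LE height reaches it.
#' @param prep repair probability in \[0,1\].
#' @param ppro processivity probability in \[0,1\].
#' @param NIDC number of insertion complexes.
#' @param f0 hole fraction seeded in the founding row, and equally the
#'   density of template gaps per site in the old-wall layers above it.
#' @param seed RNG seed.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(M = 1570L, H_target = 500L, prep = 1, ppro = 1,
                           NIDC = 10L, f0 = 0.01, seed = 1L) {
  if (M < 3) stop("configuration error: M must be >= 3")
  if (H_target < 1) stop("configuration error: H_target must be >= 1")
  for (p in c(prep, ppro))
    if (p < 0 || p > 1) stop("configuration error: probabilities in [0,1]")
  if (f0 < 0 || f0 >= 1) stop("configuration error: f0 must be in [0,1)")
  if (NIDC < 1) stop("configuration error: NIDC must be >= 1")
  structure(list(M = as.integer(M), H_target = as.integer(H_target),
                 prep = prep, ppro = ppro, NIDC = as.integer(NIDC),
                 f0 = f0, seed = as.integer(seed)),
            class = "lattice_config")
}

#' Initialize the leading-edge lattice
#'
#' The founding row is fully occupied except for a fraction `f0` of
#' independently seeded holes (exposed-end defects of the septal template);
#' all IDCs start idle.
#'
#' @param lcfg a [lattice_config()].
#' @return An object of class `lattice_state` with the LE height profile
#'   `h`, per-column defect marks and template-gap flags, the IDC table and
#'   counters.
#' @export
init_lattice <- function(lcfg) {
  set.seed(lcfg$seed)
  hole <- runif(lcfg$M) < lcfg$f0
  gap <- logical(lcfg$M)
  gap[!hole] <- runif(sum(!hole)) < lcfg$f0
  structure(list(
    h = ifelse(hole, 0L, 1L),
    marked = hole,           # exposed-end defects
    gap = gap,               # template gap at the current front site
    idcs = data.frame(col = rep(0L, lcfg$NIDC), dir = 1L, mode = "idle",
                      stringsAsFactors = FALSE),
    M = lcfg$M, fills = 0L, ticks = 0L), class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> M = %d, mean LE height %.2f rows (min %d, max %d), %d fills, %d defects\n",
              x$M, mean(x$h), min(x$h), max(x$h), x$fills, sum(x$marked)))
  invisible(x)
}

#' Defect columns of a lattice state
#' @param state a `lattice_state`.
#' @return integer vector of columns carrying an exposed-end defect.
#' @export
lattice_defects <- function(state) which(state$marked)

#' Occupancy grid of a lattice state
#'
#' Rows x columns logical matrix reconstructed from the contiguous LE
#' heights (row 1 = founding row).
#'
#' @param state a `lattice_state`.
#' @return logical matrix with `max(h)` rows.
#' @export
lattice_occupancy <- function(state) {
  nr <- max(state$h, 1L)
  outer(seq_len(nr), state$h, `<=`)
}

lat_wrap <- function(j, M) ((j - 1L) %% M) + 1L

lat_fill <- function(state, j, f0) {
  state$h[j] <- state$h[j] + 1L
  state$marked[j] <- FALSE
  state$gap[j] <- runif(1) < f0
  state$fills <- state$fills + 1L
  state
}

lat_try_insert <- function(state, j, lcfg) {
  q <- 1
  if (state$gap[j]) q <- q * lcfg$ppro
  if (state$marked[j]) q <- q * lcfg$prep
  if (q >= 1 || runif(1) < q) {
    state <- lat_fill(state, j, lcfg$f0)
    attr(state, "filled") <- TRUE
  } else {
    attr(state, "filled") <- FALSE
  }
  state
}

#' One tick of the leading-edge lattice model
#'
#' Every IDC acts once, in shuffled order. A polymerizing IDC moves one
#' column in its direction and inserts at the local front site there,
#' conforming to the front; at a template gap it continues with probability
#' `ppro`, at a defect-marked column it first needs repair (probability
#' `prep`); a failed attempt terminates the strand and marks the column
#' with an end defect. An idle IDC binds a uniformly random column of the
#' LE ring and initiates polymerization from the glycan end there with
#' probability `prep` (subject to the same gap/defect trial).
#'
#' This is the plain-R reference implementation of the rules;
#' [run_to_height()] runs the same rules in compiled code.
#'
#' @param state a [lattice_state][init_lattice()].
#' @param lcfg the [lattice_config()].
#' @return the updated state.
#' @export
lattice_step <- function(state, lcfg) {
  for (k in sample.int(nrow(state$idcs))) {
    if (state$idcs$mode[k] == "polymerizing") {
      j <- lat_wrap(state$idcs$col[k] + state$idcs$dir[k], state$M)
      state <- lat_try_insert(state, j, lcfg)
      if (attr(state, "filled")) {
        state$idcs$col[k] <- j
      } else {
        state$marked[j] <- TRUE
        state$idcs$mode[k] <- "idle"
      }
    } else {
      j0 <- sample.int(state$M, 1L)
      if (runif(1) < lcfg$prep) {
        state <- lat_try_insert(state, j0, lcfg)
        if (attr(state, "filled")) {
          state$idcs$col[k] <- j0
          state$idcs$dir[k] <- if (runif(1) < 0.5) 1L else -1L
          state$idcs$mode[k] <- "polymerizing"
        } else {
          state$marked[j0] <- TRUE
        }
      }
    }
  }
  state$ticks <- state$ticks + 1L
  state
}

#' Run the lattice model until the leading edge reaches a target height
#'
#' Iterates the insertion rules until the mean LE height reaches
#' `H_target` (500 glycan rows by default) and returns the final profile
#' and its dispersion statistics. The default engine is compiled;
#' `engine = "r"` drives the run through [lattice_step()] instead.
#'
#' @param lcfg a [lattice_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @param stall_ticks abort with a stall error after this many consecutive
#'   ticks without a fill (default 1e6).
#' @return list with `h` (final LE height profile), `roughness`, `width`,
#'   `ticks` and `fills`.
#' @export
run_to_height <- function(lcfg, engine = c("cpp", "r"), stall_ticks = 1e6) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    set.seed(lcfg$seed)
    res <- lattice_run_cpp(lcfg$M, lcfg$prep, lcfg$ppro, lcfg$NIDC, lcfg$f0,
                           lcfg$H_target, stall_ticks)
    if (res$stalled)
      stop("stall error: no fills for ", format(stall_ticks), " consecutive ticks")
    h <- res$h
    ticks <- res$ticks
    fills <- res$fills
  } else {
    state <- init_lattice(lcfg)
    idle <- 0
    target <- lcfg$H_target * lcfg$M
    while (sum(state$h) < target) {
      before <- state$fills
      state <- lattice_step(state, lcfg)
      idle <- if (state$fills == before) idle + 1 else 0
      if (idle >= stall_ticks)
        stop("stall error: no fills for ", format(stall_ticks),
             " consecutive ticks")
    }
    h <- state$h
    ticks <- state$ticks
    fills <- state$fills
  }
  rw <- roughness_width(h)
  list(h = h, roughness = rw[["roughness"]], width = rw[["width"]],
       ticks = ticks, fills = fills)
}

#' Roughness and width of a leading-edge height profile
#'
#' Width is the RMS deviation of the column heights,
#' `W = sqrt(mean((h - mean(h))^2))` (rows); roughness is the relative
#' width `W / mean(h)` (dimensionless). Both are reported so alternative
#' definitions can be post-computed.
#'
#' @param state a `lattice_state`, or a numeric height profile.
#' @return named numeric vector `c(roughness, width)`.
#' @export
roughness_width <- function(state) {
  h <- if (inherits(state, "lattice_state")) state$h else state
  m <- mean(h)
  if (m == 0) stop("undefined roughness: mean height is zero")
  W <- sqrt(mean((h - m)^2))
  c(roughness = W / m, width = W)
}

#' Replicate lattice runs for one parameter set
#'
#' Runs `reps` independent replicates (seeds derived from `lcfg$seed`) and
#' collects roughness and width, the batch protocol used for
#' roughness/width phase diagrams (100 replicates per parameter set).
#'
#' @param lcfg a [lattice_config()].
#' @param reps number of replicates.
#' @return data.frame with columns rep, roughness, width, ticks.
#' @export
run_lattice_batch <- function(lcfg, reps = 100L) {
  set.seed(lcfg$seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    lc <- lcfg
    lc$seed <- seeds[i]
    r <- run_to_height(lc)
    out[[i]] <- data.frame(rep = i, roughness = r$roughness,
                           width = r$width, ticks = r$ticks)
  }
  do.call(rbind, out)
}
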