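# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never disturbs the user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Classed errors so callers can distinguish sizing/geometry/config failures.
nt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nervetrace_error")))
}

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m == 0L | m == 1L)
}

assert_mask <- function(m, arg = "mask") {
  if (!is_binary_matrix(m)) {
    nt_stop(sprintf("`%s` must be a binary (0/1) matrix", arg),
            "nervetrace_type_error")
  }
  invisible(m)
}

# Apply an EBImage operation to a row/column-indexed matrix. EBImage stores
# images x-major (first dimension = column), so transpose on the way in/out.
eb_op <- function(m, f) {
  t(EBImage::imageData(f(EBImage::as.Image(t(m)))))
}

# 8-connected component labelling (EBImage::bwlabel is 4-connected).
# Vectorised frontier BFS on the flat pixel index; masks here are small
# relative to the frame so this is never a hot path.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  # neighbour offsets in flat (column-major) index, with row-wrap guards
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  row_of <- function(idx) ((idx - 1L) %% h) + 1L
  nextlab <- 0L
  todo <- fg
  inmask <- logical(h * w)
  inmask[fg] <- TRUE
  for (s in fg) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + offs
      rows <- rep(row_of(frontier), each = 8L) + drow
      ok <- cand >= 1L & cand <= h * w & rows >= 1L & rows <= h
      ok[ok] <- ok[ok] & row_of(cand[ok]) == rows[ok]
      cand <- unique(cand[ok])
      cand <- cand[inmask[cand] & lab[cand] == 0L]
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab
}
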