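# Independent reference implementations used as oracles. These deliberately
# re-derive everything from first definitions (plain R, no package internals)
# so that agreement with the package is a genuine cross-check.

random_rna <- function(n, min_len = 15, max_len = 75) {
  vapply(sample(seq.int(min_len, max_len), n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Levenshtein distance by the textbook dynamic program.
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, integer(length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

# Pair table and position classes from a dot-bracket string, via an explicit
# stack; classes: "paired", "hairpin" (loop member), "unpaired" (other).
oracle_parse <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  partner <- integer(n)
  st <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      k <- st[length(st)]
      st <- st[-length(st)]
      partner[i] <- k
      partner[k] <- i
    }
  }
  cls <- ifelse(partner > 0, "paired", "unpaired")
  loops <- list()
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i + 1 && all(partner[(i + 1):(j - 1)] == 0)) {
      loops[[length(loops) + 1]] <- (i + 1):(j - 1)
      cls[(i + 1):(j - 1)] <- "hairpin"
    }
  }
  list(partner = partner, cls = cls, loops = loops)
}

# Exhaustive window/loop scan implementing the site rules directly.
oracle_sites <- function(seq, db, specs) {
  ch <- strsplit(seq, "")[[1]]
  P <- oracle_parse(db)
  rows <- list()
  for (sp in specs) {
    motif <- strsplit(sp@motif, "")[[1]]
    w <- length(motif)
    if (sp@context == "unpaired-region") {
      free <- P$cls == "unpaired"
      runs <- rle(free)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      for (r in which(runs$values)) {
        if (runs$lengths[r] < w) next
        best <- NULL
        for (k in starts[r]:(ends[r] - w + 1)) {
          if (k + w - 1 > ends[r]) next
          mm <- sum(ch[k:(k + w - 1)] != motif)
          if (mm > sp@maxMismatch) next
          alpha <- sp@mismatchFactor^mm
          if (alpha > 0 && (is.null(best) || alpha > best$alpha))
            best <- list(k = k, alpha = alpha)
        }
        if (!is.null(best))
          rows[[length(rows) + 1]] <- data.frame(
            activity = sp@index, start = best$k, end = best$k + w - 1,
            alpha = best$alpha)
      }
    } else {
      for (loop in P$loops) {
        dev <- abs(length(loop) - sp@targetLoopSize)
        if (dev > sp@maxLoopDeviation) next
        if (length(loop) < w) next
        best <- NULL
        for (k in loop[1]:(loop[length(loop)] - w + 1)) {
          mm <- sum(ch[k:(k + w - 1)] != motif)
          if (mm > sp@maxMismatch) next
          alpha <- sp@mismatchFactor^mm * sp@loopSizeFactor^dev
          if (alpha > 0 && (is.null(best) || alpha > best$alpha))
            best <- list(k = k, alpha = alpha)
        }
        if (!is.null(best))
          rows[[length(rows) + 1]] <- data.frame(
            activity = sp@index, start = best$k, end = best$k + w - 1,
            alpha = best$alpha)
      }
    }
  }
  if (!length(rows))
    return(data.frame(activity = integer(), start = integer(),
                      end = integer(), alpha = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$activity, out$start), , drop = FALSE]
}

# Build a lattice directly from a matrix of sequences ("" = empty).
make_lattice <- function(grid, params) {
  new("ReplicatorLattice", grid = grid, generation = 0L, parity = 0L,
      params = params, foldCache = new.env(parent = emptyenv()))
}

# Small parameter set for fast tests.
test_params <- function(width = 12, height = 12, ...) {
  simParams(width = width, height = height, ...)
}

# One full generation of lattice dynamics, re-implemented in plain R from
# the update definitions (site draws with replacement; degradation;
# claim-proportional replication; no diffusion). Used as the independent
# reference for the compiled engine's occupancy dynamics.
reference_generation <- function(grid, params, ann) {
  W <- nrow(grid); H <- ncol(grid)
  info <- function(s) ann[match(s, ann$sequence), ]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  revcomp <- function(s) chartr("ACGU", "UGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  metab <- function(x, y) {
    tot <- c(0, 0, 0)
    for (dx in -params@h:params@h) for (dy in -params@h:params@h) {
      s <- grid[wrap(x + dx, W), wrap(y + dy, H)]
      if (s != "") {
        r <- info(s)
        tot <- tot + c(r$a1, r$a2, r$a3)
      }
    }
    if (any(tot <= 0)) 0 else prod(tot)^(1 / 3)
  }
  for (u in seq_len(W * H)) {
    site <- sample.int(W * H, 1)
    x <- ((site - 1) %% W) + 1
    y <- ((site - 1) %/% W) + 1
    s <- grid[x, y]
    if (s != "") {
      if (runif(1) < info(s)$pdeg) grid[x, y] <- ""
    } else {
      cl <- numeric(0); cs <- character(0)
      rr <- params@replicationRadius
      for (dx in -rr:rr) for (dy in -rr:rr) {
        if (dx == 0 && dy == 0) next
        nx <- wrap(x + dx, W); ny <- wrap(y + dy, H)
        sn <- grid[nx, ny]
        if (sn == "") next
        M <- metab(nx, ny)
        if (M <= 0) next
        C <- M * info(sn)$R
        if (C > 0) { cl <- c(cl, C); cs <- c(cs, sn) }
      }
      if (!length(cl)) next
      probs <- c(params@claimEmpty, cl) / (params@claimEmpty + sum(cl))
      pick <- sample.int(length(probs), 1, prob = probs)
      if (pick > 1) grid[x, y] <- revcomp(cs[pick - 1])  # mutation rates 0
    }
  }
  grid
}
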