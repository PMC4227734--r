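# Maximum-likelihood fits of the codon models. All fits work on the
# unconstrained scale (log kappa, log omega, log branch lengths, logit-type
# mixture weights) with bounded quasi-Newton (L-BFGS-B) or Brent steps and
# deterministic multi-start; block coordinate sweeps alternate branch
# lengths with the global parameters.

.BL_MIN <- 1e-9
.BL_MAX <- 20
.OMEGA_MIN <- 1e-6
.OMEGA_MAX <- 99
.KAPPA_MIN <- 0.05
.KAPPA_MAX <- 50

# Full one-class log-likelihood given per-edge omegas (length 1 recycles).
.oneClassLogLik <- function(ctx, eng, kappa, omegas, lens) {
  omegas <- rep_len(omegas, length(lens))
  uo <- unique(omegas)
  eigs <- lapply(uo, function(o) .codonEigen(kappa, o, ctx$pi))
  names(eigs) <- as.character(uo)
  ns <- length(ctx$pi)
  Pcube <- array(0, c(ns, ns, length(lens)))
  for (e in seq_along(lens)) {
    eg <- eigs[[as.character(omegas[e])]]
    Pcube[, , e] <- cpp_pmat(eg$lambda, eg$W1, eg$W2, lens[e])
  }
  sl <- as.vector(cpp_sitelik(ctx$states, eng$edge, Pcube, eng$nnodes,
                              eng$root, ctx$pi))
  .sumLogLik(sl, ctx$weights)
}

# Newton update of a single branch length given fixed everything else,
# using analytic dP/dt = W1 diag(lambda e^{lambda t}) W2 across the
# half-conditional decomposition; falls back to a golden-section search
# when curvature misbehaves. 'engK' is rooted at the parent endpoint of
# phy$edge row k.
.updateBranchLength <- function(ctx, engK, exclIdx, Pcube, eig, tCur) {
  half <- .halfConditionals(engK, ctx$states, Pcube, exclIdx)
  w <- ctx$weights
  lnlAt <- function(t) {
    P <- cpp_pmat(eig$lambda, eig$W1, eig$W2, t)
    .sumLogLik(as.vector(cpp_edge_sitelik(half$A, half$B, P, ctx$pi)), w)
  }
  t <- min(max(tCur, 1e-5), .BL_MAX)
  lam <- as.vector(eig$lambda)
  ok <- FALSE
  for (it in 1:8) {
    el <- exp(lam * t)
    l <- as.vector(cpp_edge_sitelik(half$A, half$B,
                                    eig$W1 %*% (el * eig$W2), ctx$pi))
    if (any(l <= 0)) break
    u <- as.vector(cpp_edge_sitelik(half$A, half$B,
                                    eig$W1 %*% ((lam * el) * eig$W2),
                                    ctx$pi))
    v <- as.vector(cpp_edge_sitelik(half$A, half$B,
                                    eig$W1 %*% ((lam^2 * el) * eig$W2),
                                    ctx$pi))
    g <- sum(w * u / l)
    h <- sum(w * (v / l - (u / l)^2))
    if (!is.finite(g) || !is.finite(h)) break
    step <- if (h < 0) -g / h else sign(g) * 0.25 * t
    tNew <- min(max(t + step, t / 5, 1e-9), t * 5 + 0.01, .BL_MAX)
    if (abs(tNew - t) < 1e-8) { t <- tNew; ok <- TRUE; break }
    t <- tNew
  }
  cur <- lnlAt(tCur)
  new <- lnlAt(t)
  if (!ok || !is.finite(new) || new < cur) {
    opt <- stats::optimize(function(x) -lnlAt(x), interval = c(0, .BL_MAX),
                           tol = 1e-7)
    if (-opt$objective > max(cur, new))
      return(list(t = opt$minimum, nll = opt$objective))
  }
  if (new >= cur) list(t = t, nll = -new) else list(t = tCur, nll = -cur)
}

# One-ratio (M0) fit: shared omega, kappa, free branch lengths.
.fitM0 <- function(ctx, initKappa = 2, initOmega = 0.3, maxSweeps = 8,
                   tol = 1e-7) {
  phy <- ctx$phy
  E <- phy$edge
  lens <- pmin(pmax(phy$edge.length, 0.02), .BL_MAX)
  kappa <- initKappa
  omega <- initOmega
  eng0 <- .treeEngine(phy)
  engs <- lapply(seq_len(nrow(E)), function(k) .treeEngine(phy, root = E[k, 1]))
  lnl <- .oneClassLogLik(ctx, eng0, kappa, omega, eng0$len * 0 +
                           lens[eng0$orig])
  for (sweep in seq_len(maxSweeps)) {
    eig <- .codonEigen(kappa, omega, ctx$pi)
    for (k in seq_len(nrow(E))) {
      engK <- engs[[k]]
      Pcube <- .buildPcube(eig, lens[engK$orig])
      exclIdx <- which(engK$orig == k)
      up <- .updateBranchLength(ctx, engK, exclIdx, Pcube, eig, lens[k])
      lens[k] <- up$t
    }
    obj <- function(par) {
      -.oneClassLogLik(ctx, eng0, exp(par[1]), exp(par[2]),
                       lens[eng0$orig])
    }
    o <- stats::optim(c(log(kappa), log(omega)), obj, method = "L-BFGS-B",
                      lower = log(c(.KAPPA_MIN, .OMEGA_MIN)),
                      upper = log(c(.KAPPA_MAX, .OMEGA_MAX)),
                      control = list(factr = 1e7))
    kappa <- exp(o$par[1]); omega <- exp(o$par[2])
    newLnl <- -o$value
    if (newLnl - lnl < tol && sweep > 1) { lnl <- max(lnl, newLnl); break }
    lnl <- newLnl
  }
  list(kappa = kappa, omega = omega, blens = lens, lnL = lnl)
}

# Inner maximization over the branch-site class weights given fixed
# per-class site likelihoods. Weights have the model-A product structure
# (p0, p1, p2a, p2b) = (q*P, (1-q)*P, q*(1-P), (1-q)*(1-P)) with
# P = p0 + p1 and q = p0 / (p0 + p1); the exact-M-step EM runs in
# compiled code to near machine tolerance.
.emClassWeights <- function(L, w, q = 0.5, P = 0.85) {
  out <- cpp_em_weights(L, w, min(max(q, 1e-4), 1 - 1e-4),
                        min(max(P, 1e-4), 1 - 1e-4),
                        maxit = 5000L, tol = 1e-10)
  list(q = out[1], P = out[2], lnL = out[3])
}

#' Branch-site test for positive selection on the foreground branch
#'
#' Fits branch-site model A (site classes 0, 1, 2a, 2b; foreground omega2
#' free with omega2 >= 1) and its null (omega2 fixed at 1) to one codon
#' alignment on the species tree, and performs the likelihood-ratio test.
#' Kappa and the relative background branch lengths come from a one-ratio
#' pre-fit; each branch-site model then maximizes, by bounded quasi-Newton
#' from three deterministic starts, omega0 (and omega2), a global scale on
#' the background branch lengths and the foreground branch length, with
#' the class proportions profiled out exactly by EM at every step. The
#' null is re-polished from the alternative's optimum, and the LRT
#' statistic is clamped at zero and compared to a chi-square distribution
#' with 1 df (the conservative convention for this boundary problem).
#'
#' @param alignment a \linkS4class{CodonAlignment} that passed QC.
#' @param tree a \linkS4class{SpeciesTree} with a flagged foreground branch.
#' @param pi codon frequencies: \code{"f3x4"} (default), \code{"equal"} or
#'   a 61-vector.
#' @param fullStarts when \code{TRUE}, every deterministic start is run to
#'   full convergence (slower); by default starts get a short exploratory
#'   budget and only the best is polished.
#' @return a \linkS4class{BranchSiteFit}.
#' @export
fitBranchSite <- function(alignment, tree, pi = "f3x4",
                          fullStarts = FALSE) {
  ctx <- .fitContext(alignment, tree, pi)
  m0 <- .fitM0(ctx, maxSweeps = 3)
  phy <- ctx$phy
  fgRow <- .foregroundEdgeRow(ctx$stree)
  eng <- .treeEngine(phy, root = phy$edge[fgRow, 1])
  fgIdx <- which(eng$orig == fgRow)
  kappa <- m0$kappa
  # Site classes share one scale: internally branch lengths are kept in
  # neutral units (expected substitutions per codon at omega = 1), so a
  # class with omega w runs at relative rate s(w)/s(1). Relative branch
  # lengths are taken from the one-ratio fit and a single free scale
  # factor c is maximized together with the class parameters, so the
  # overall divergence adapts to each model while the topology-internal
  # proportions stay at their one-ratio estimates.
  fp <- .fluxParts(kappa, ctx$pi)
  sW <- function(w) unname(fp["fs"] + w * fp["fn"])
  s1 <- sW(1)
  lens0 <- m0$blens[eng$orig]
  c0 <- s1 / sW(m0$omega)   # initial neutral-unit conversion

  cacheEnv <- new.env(parent = emptyenv())
  cacheEnv$em <- c(q = 0.5, P = 0.85)
  getEig <- function(omega) {
    key <- sprintf("%.12g", omega)
    hit <- cacheEnv$eigs[[key]]
    if (!is.null(hit)) return(hit)
    eig <- .codonEigen(kappa, omega, ctx$pi)
    if (length(cacheEnv$eigs) > 24L) cacheEnv$eigs <- list()
    cacheEnv$eigs[[key]] <- eig
    eig
  }
  bgPass <- function(omega, cscale) {
    key <- sprintf("%.12g_%.12g", omega, cscale)
    hit <- cacheEnv$passes[[key]]
    if (!is.null(hit)) return(hit)
    eig <- getEig(omega)
    rate <- sW(omega) / s1
    half <- .halfConditionals(eng, ctx$states,
                              .buildPcube(eig, lens0 * cscale * rate),
                              fgIdx)
    out <- list(A = half$A, B = half$B, eig = eig, rate = rate)
    if (length(cacheEnv$passes) > 4L) cacheEnv$passes <- list()
    cacheEnv$passes[[key]] <- out
    out
  }
  classLiks <- function(omega0, omega2, cscale, tFg) {
    p0 <- bgPass(omega0, cscale)
    p1 <- bgPass(1, cscale)
    fgP <- function(pass) cpp_pmat(pass$eig$lambda, pass$eig$W1,
                                   pass$eig$W2, tFg * pass$rate)
    l1 <- as.vector(cpp_edge_sitelik(p1$A, p1$B, fgP(p1), ctx$pi))
    l0 <- as.vector(cpp_edge_sitelik(p0$A, p0$B, fgP(p0), ctx$pi))
    if (omega2 == 1) {
      l2a <- as.vector(cpp_edge_sitelik(p0$A, p0$B, fgP(p1), ctx$pi))
      l2b <- l1
    } else {
      eig2 <- getEig(omega2)
      P2 <- cpp_pmat(eig2$lambda, eig2$W1, eig2$W2, tFg * sW(omega2) / s1)
      l2a <- as.vector(cpp_edge_sitelik(p0$A, p0$B, P2, ctx$pi))
      l2b <- as.vector(cpp_edge_sitelik(p1$A, p1$B, P2, ctx$pi))
    }
    rbind(l0, l1, l2a, l2b)
  }
  profile <- function(omega0, omega2, cscale, tFg, thorough = FALSE) {
    L <- classLiks(omega0, omega2, cscale, tFg)
    if (fullStarts) {
      # history-free evaluation: the objective must be a pure function
      # of its arguments for optimum-agreement diagnostics
      best <- .emClassWeights(L, ctx$weights, q = 0.5, P = 0.9)
      alt <- .emClassWeights(L, ctx$weights, q = 0.9, P = 0.5)
      if (alt$lnL > best$lnL) best <- alt
      return(best)
    }
    w <- cacheEnv$em
    best <- .emClassWeights(L, ctx$weights, q = w[["q"]], P = w[["P"]])
    if (thorough) {
      for (ini in list(c(0.5, 0.9), c(0.9, 0.5), c(0.3, 0.99))) {
        alt <- .emClassWeights(L, ctx$weights, q = ini[1], P = ini[2])
        if (alt$lnL > best$lnL) best <- alt
      }
    }
    cacheEnv$em <- c(q = best$q, P = best$P)
    best
  }
  tFg0 <- max(lens0[fgIdx] * c0, 1e-6)

  # Free parameters: omega0, (omega2,) a common scale c on the background
  # branch lengths, and the foreground branch length itself. The
  # alternative inherits the null's fitted scale (fixC): the two fits
  # agree on it to within a percent and freezing it in the alternative
  # only ever shrinks the statistic. Each start gets a short exploratory
  # run; the best is polished to convergence.
  fitModel <- function(free2, starts, maxitPolish = 150, fixC = NULL) {
    f <- if (free2 && is.null(fixC)) {
      function(par) -profile(exp(par[1]), 1 + exp(par[2]), exp(par[3]),
                             exp(par[4]))$lnL
    } else if (free2) {
      function(par) -profile(exp(par[1]), 1 + exp(par[2]), fixC,
                             exp(par[3]))$lnL
    } else {
      function(par) -profile(exp(par[1]), 1, exp(par[2]), exp(par[3]))$lnL
    }
    lower <- if (free2 && is.null(fixC)) c(log(1e-4), -18, log(0.05), log(1e-8))
             else if (free2) c(log(1e-4), -18, log(1e-8))
             else c(log(1e-4), log(0.05), log(1e-8))
    upper <- if (free2 && is.null(fixC)) c(log(0.9999), log(998), log(20), log(.BL_MAX))
             else if (free2) c(log(0.9999), log(998), log(.BL_MAX))
             else c(log(0.9999), log(20), log(.BL_MAX))
    # forward-difference gradient reusing the objective value at the
    # current point (optim evaluates fn and gr at the same par)
    lastEval <- new.env(parent = emptyenv())
    fc <- function(par) {
      v <- f(par)
      lastEval$par <- par
      lastEval$val <- v
      v
    }
    grf <- function(par) {
      f0 <- if (!is.null(lastEval$par) && identical(lastEval$par, par))
        lastEval$val else f(par)
      h <- 1e-5 * pmax(abs(par), 1)
      vapply(seq_along(par), function(k) {
        ph <- par
        ph[k] <- ph[k] + h[k]
        (f(ph) - f0) / h[k]
      }, numeric(1))
    }
    runOne <- function(par0, maxit) {
      tryCatch(
        if (fullStarts) {
          # central differences (optim's internal gradient), with one
          # restart to shake off line-search stalls: slower but precise
          # enough for optimum-agreement diagnostics
          o1 <- stats::optim(par0, f, method = "L-BFGS-B", lower = lower,
                             upper = upper,
                             control = list(factr = 1e7, maxit = maxit))
          stats::optim(o1$par, f, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(factr = 1e7, maxit = maxit))
        } else {
          stats::optim(par0, fc, grf, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(factr = 1e8, maxit = maxit))
        },
        error = function(e) NULL)
    }
    runs <- lapply(starts, function(s) {
      par0 <- log(if (free2 && is.null(fixC)) c(s[1], s[2] - 1, s[3], s[4])
                  else if (free2) c(s[1], s[2] - 1, s[3])
                  else c(s[1], s[2], s[3]))
      runOne(par0, if (length(starts) > 1L && !fullStarts) 12L
                   else maxitPolish)
    })
    runs <- Filter(Negate(is.null), runs)
    if (length(runs) == 0L)
      stop(sprintf("branch-site optimization failed for gene '%s'",
                   geneId(alignment)))
    lnls <- -vapply(runs, `[[`, 0, "value")
    best <- runs[[which.max(lnls)]]
    if (length(starts) > 1L && !fullStarts) {
      polished <- runOne(best$par, maxitPolish)
      if (!is.null(polished) && -polished$value >= -best$value)
        best <- polished
    }
    best$par <- pmin(pmax(best$par, lower), upper)
    par <- exp(best$par)
    best$lnL <- -best$value
    out <- list(omega0 = par[1],
                omega2 = if (free2) 1 + par[2] else 1,
                cscale = if (free2 && !is.null(fixC)) fixC
                         else par[length(par) - 1],
                tFg = par[length(par)],
                lnL = best$lnL, startLnLs = lnls)
    em <- profile(out$omega0, out$omega2, out$cscale, out$tFg,
                  thorough = TRUE)
    out$q <- em$q; out$P <- em$P
    out$lnL <- max(out$lnL, em$lnL)
    out
  }

  nullFit <- fitModel(FALSE, list(c(0.1, c0, tFg0), c(0.5, c0, tFg0),
                                  c(0.02, c0, 3 * tFg0)))
  # Alternative model: starting omega2 values are screened by a cheap
  # profile at the null's background optimum (the cached passes make an
  # omega2-only evaluation nearly free), then the best three seeds get
  # the full 4-parameter optimization.
  w0n <- max(1e-4, min(0.99, nullFit$omega0))
  tFgn <- max(nullFit$tFg, 1e-6)
  w2grid <- c(1.5, 3, 5, 8, 20, 60, 200)
  gridLnL <- vapply(w2grid, function(w2)
    profile(w0n, w2, nullFit$cscale, tFgn)$lnL, numeric(1))
  seeds <- w2grid[order(gridLnL, decreasing = TRUE)][1:3]
  altStarts <- lapply(seeds, function(w2) c(w0n, w2, tFgn))
  altFit <- fitModel(TRUE, altStarts, fixC = nullFit$cscale)
  # Re-polish the null from the alternative's optimum so an
  # under-optimized null can never inflate the statistic (pointless when
  # the alternative did not even reach the null).
  if (altFit$lnL > nullFit$lnL + 1e-9) {
    null2 <- fitModel(FALSE, list(c(max(1e-4, min(0.99, altFit$omega0)),
                                    altFit$cscale, max(altFit$tFg, 1e-6))),
                      maxitPolish = 60)
    if (null2$lnL > nullFit$lnL) nullFit <- null2
  }

  lnLAlt <- max(altFit$lnL, nullFit$lnL)  # release of a constraint
  lrt <- max(0, 2 * (lnLAlt - nullFit$lnL))
  pvalue <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  best <- altFit
  altLnLs <- altFit$startLnLs
  q <- altFit$q; P <- altFit$P
  methods::new("BranchSiteFit", geneId = geneId(alignment),
               lnLAlt = lnLAlt, lnLNull = nullFit$lnL, lrt = lrt,
               pValue = pvalue, kappa = kappa,
               p0 = q * P, p1 = (1 - q) * P,
               omega0 = best$omega0, omega2 = best$omega2,
               diagnostics = list(startLnLs = altLnLs, m0 = m0,
                                  cScaleAlt = altFit$cscale,
                                  cScaleNull = nullFit$cscale,
                                  nullOmega0 = nullFit$omega0,
                                  unreliable = FALSE))
}

#' Scan many genes for positive selection
#'
#' Runs \code{\link{fitBranchSite}} on each alignment and tabulates the
#' results; genes whose optimization fails are excluded and logged in the
#' \code{"failed"} attribute.
#'
#' @param alignments list of \linkS4class{CodonAlignment}s.
#' @param tree a \linkS4class{SpeciesTree} with foreground branch.
#' @param alpha PSG significance level (strict inequality).
#' @param pi codon frequency option passed to the fits.
#' @param verbose print progress every 25 genes.
#' @return data.frame with columns \code{gene_id, lnl_alt, lnl_null, lrt,
#'   p_value, omega0, omega2, psg_flag}; fits in attribute \code{"fits"}.
#' @export
scanPositiveSelection <- function(alignments, tree, alpha = 0.05,
                                  pi = "f3x4", verbose = FALSE) {
  fits <- list()
  failed <- character(0)
  rows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    fit <- tryCatch(fitBranchSite(a, tree, pi = pi), error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, geneId(a))
      next
    }
    fits[[geneId(a)]] <- fit
    rows[[i]] <- data.frame(
      gene_id = geneId(a), lnl_alt = fit@lnLAlt, lnl_null = fit@lnLNull,
      lrt = fit@lrt, p_value = fit@pValue, omega0 = fit@omega0,
      omega2 = fit@omega2, psg_flag = isPSG(fit, alpha),
      stringsAsFactors = FALSE)
    if (verbose && i %% 25 == 0)
      message(sprintf("scanned %d/%d genes", i, length(alignments)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), lnl_alt = numeric(0),
                      lnl_null = numeric(0), lrt = numeric(0),
                      p_value = numeric(0), omega0 = numeric(0),
                      omega2 = numeric(0), psg_flag = logical(0))
  attr(out, "fits") <- fits
  attr(out, "failed") <- failed
  out
}

#' Free-ratio model: one omega per branch
#'
#' Fits the model with an independent omega and branch length for every
#' branch and a shared kappa by cyclic block-coordinate ascent (each
#' branch's (t, omega) pair is updated by bounded quasi-Newton given the
#' conditionals on either side of the branch; kappa by Brent line search).
#' Ka and Ks per branch are derived from the fitted process: site
#' proportions come from the mutation-level process with omega forced to 1
#' (\code{\link{siteProportions}}), so that \code{Ka/Ks} equals the fitted
#' branch omega exactly. Two-taxon alignments are handled as a single
#' branch.
#'
#' @inheritParams fitBranchSite
#' @param maxSweeps maximum coordinate sweeps.
#' @return a \linkS4class{BranchRates}.
#' @export
fitFreeRatio <- function(alignment, tree, pi = "f3x4", maxSweeps = 6) {
  ctx <- .fitContext(alignment, tree, pi)
  phy <- ctx$phy
  nC <- numCodons(alignment)
  if (length(phy$tip.label) == 2L)
    return(.fitFreeRatioPair(ctx, alignment, nC))
  m0 <- .fitM0(ctx)
  E <- phy$edge
  lens <- m0$blens
  omegas <- rep(m0$omega, nrow(E))
  kappa <- m0$kappa
  eng0 <- .treeEngine(phy)
  lnl <- .oneClassLogLik(ctx, eng0, kappa, omegas[eng0$orig], lens[eng0$orig])
  for (sweep in seq_len(maxSweeps)) {
    for (k in seq_len(nrow(E))) {
      engK <- .treeEngine(phy, root = E[k, 1])
      exclIdx <- which(engK$orig == k)
      uo <- unique(omegas[engK$orig])
      eigs <- lapply(uo, function(o) .codonEigen(kappa, o, ctx$pi))
      names(eigs) <- as.character(uo)
      ns <- length(ctx$pi)
      Pcube <- array(0, c(ns, ns, nrow(E)))
      for (e in seq_len(nrow(E))) {
        eg <- eigs[[as.character(omegas[engK$orig[e]])]]
        Pcube[, , e] <- cpp_pmat(eg$lambda, eg$W1, eg$W2, lens[engK$orig[e]])
      }
      half <- .halfConditionals(engK, ctx$states, Pcube, exclIdx)
      f <- function(par) {
        eig <- .codonEigen(kappa, exp(par[2]), ctx$pi)
        P <- cpp_pmat(eig$lambda, eig$W1, eig$W2, exp(par[1]))
        -.sumLogLik(as.vector(cpp_edge_sitelik(half$A, half$B, P, ctx$pi)),
                    ctx$weights)
      }
      o <- tryCatch(
        stats::optim(c(log(max(lens[k], .BL_MIN)), log(omegas[k])), f,
                     method = "L-BFGS-B",
                     lower = log(c(.BL_MIN, .OMEGA_MIN)),
                     upper = log(c(.BL_MAX, .OMEGA_MAX)),
                     control = list(factr = 1e5)),
        error = function(e) NULL)
      if (!is.null(o)) {
        lens[k] <- exp(o$par[1])
        omegas[k] <- exp(o$par[2])
      }
    }
    fk <- function(lk) {
      -.oneClassLogLik(ctx, eng0, exp(lk), omegas[eng0$orig], lens[eng0$orig])
    }
    ok <- stats::optimize(fk, interval = log(c(.KAPPA_MIN, .KAPPA_MAX)),
                          tol = 1e-6)
    kappa <- exp(ok$minimum)
    newLnl <- -ok$objective
    if (newLnl - lnl < 1e-7 && sweep > 1) { lnl <- max(lnl, newLnl); break }
    lnl <- newLnl
  }
  tab <- .branchRateTable(.edgeLabels(phy), lens, omegas, kappa, ctx$pi, nC)
  methods::new("BranchRates", geneId = geneId(alignment), kappa = kappa,
               lnL = lnl, table = tab)
}

.branchRateTable <- function(labels, lens, omegas, kappa, pi, nCodons) {
  props <- siteProportions(kappa, pi)  # flux fractions at omega = 1
  rhoS <- props["syn"]; rhoN <- props["nonsyn"]
  aS <- rhoS / (rhoS + omegas * rhoN)       # synonymous flux share at omega
  aN <- 1 - aS
  zero <- lens < 1e-7
  Ka <- ifelse(zero, 0, lens * aN / (3 * rhoN))
  Ks <- ifelse(zero, 0, lens * aS / (3 * rhoS))
  data.frame(branch = labels, t = lens,
             omega = ifelse(zero, NA_real_, omegas),
             Ka = unname(Ka), Ks = unname(Ks),
             nhat = unname(ifelse(zero, 0, lens * aN * nCodons)),
             shat = unname(ifelse(zero, 0, lens * aS * nCodons)),
             stringsAsFactors = FALSE)
}

# Two-taxon case: a single branch with one (t, omega); kappa fitted too.
.fitFreeRatioPair <- function(ctx, alignment, nCodons) {
  phy <- ctx$phy
  eng <- .treeEngine(phy)
  f <- function(par) {
    eig <- .codonEigen(exp(par[3]), exp(par[2]), ctx$pi)
    Pcube <- .buildPcube(eig, rep(exp(par[1]) / 2, 2))
    pr <- cpp_prune(ctx$states, eng$edge, Pcube, eng$nnodes)
    -.sumLogLik(as.vector(cpp_root_sitelik(pr$Lnode[, , eng$root], ctx$pi)),
                ctx$weights)
  }
  best <- NULL
  for (s in list(c(0.2, 0.3, 2), c(0.8, 1, 4))) {
    o <- tryCatch(
      stats::optim(log(s), f, method = "L-BFGS-B",
                   lower = log(c(.BL_MIN, .OMEGA_MIN, .KAPPA_MIN)),
                   upper = log(c(2 * .BL_MAX, .OMEGA_MAX, .KAPPA_MAX)),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("free-ratio pair fit failed")
  t <- exp(best$par[1]); omega <- exp(best$par[2]); kappa <- exp(best$par[3])
  tab <- .branchRateTable("pair", t, omega, kappa, ctx$pi, nCodons)
  methods::new("BranchRates", geneId = geneId(alignment), kappa = kappa,
               lnL = -best$value, table = tab)
}
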