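# SPR topology moves with lazy scoring. A candidate move prunes the
# subtree behind node r attached at internal node p, dissolves p, and
# regrafts onto a target edge within `radius` edges of the original
# location. Candidates are scored approximately against cached directed
# messages (the pruned subtree's vector is exact; the remaining-tree vector
# toward each target is rebuilt incrementally along the walk), then the
# best candidates are re-evaluated exactly and accepted only if the true
# log-likelihood improves.

spr_scan <- function(ct, cache, model, weights, cur_loglik, radius = 5) {
  M <- cache$M; SC <- cache$SC
  pi <- model$pi
  cands <- list()
  score_target <- function(msub, scsub, tsub, b, bsc, ta, maway, scaway, tb) {
    x <- (pi * (ptr(model, ta) %*% b)) *
      (ptr(model, tb) %*% maway) *
      (ptr(model, tsub) %*% msub)
    v <- .colSums(x, nrow(x), ncol(x))
    sum(weights * (log(v) + bsc + scaway + scsub))
  }
  for (p in (ct$ntip + 1L):ct$ntot) {
    for (r in ct$adj[[p]]) {
      # subtree behind r, attachment p
      sl <- ct_slot(ct, r, p)
      msub <- M[[r]][[sl]]; scsub <- SC[[r]][[sl]]
      tsub <- ct$alen[[r]][sl]
      nb <- setdiff(ct$adj[[p]], r)
      x1 <- nb[1]; x2 <- nb[2]
      t1 <- ct_brlen(ct, p, x1); t2 <- ct_brlen(ct, p, x2)
      m1 <- M[[x1]][[ct_slot(ct, x1, p)]]; s1 <- SC[[x1]][[ct_slot(ct, x1, p)]]
      m2 <- M[[x2]][[ct_slot(ct, x2, p)]]; s2 <- SC[[x2]][[ct_slot(ct, x2, p)]]
      # walk outward in both directions; queue entries describe target edge
      # (prev, node): B = corrected rest-tree message behind prev
      queue <- list()
      if (x2 > ct$ntip) {
        queue[[length(queue) + 1L]] <- list(prev = x1, node = x2, B = m1,
                                            Bsc = s1, tprev = t1 + t2, depth = 1L,
                                            enter = TRUE)
      }
      if (x1 > ct$ntip) {
        queue[[length(queue) + 1L]] <- list(prev = x2, node = x1, B = m2,
                                            Bsc = s2, tprev = t1 + t2, depth = 1L,
                                            enter = TRUE)
      }
      while (length(queue)) {
        st <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        node <- st$node; prev <- st$prev
        others <- setdiff(ct$adj[[node]], c(prev, p))
        for (z in others) {
          tz <- ct_brlen(ct, node, z)
          o <- setdiff(others, z)
          # corrected message behind `node` toward z
          if (length(o) == 1) {
            to <- ct_brlen(ct, node, o)
            mo <- M[[o]][[ct_slot(ct, o, node)]]
            so <- SC[[o]][[ct_slot(ct, o, node)]]
            b <- (ptr(model, st$tprev) %*% st$B) * (ptr(model, to) %*% mo)
            bsc <- st$Bsc + so
          } else {
            b <- ptr(model, st$tprev) %*% st$B
            bsc <- st$Bsc
          }
          mx <- .colSums(b, nrow(b), ncol(b)); mx[mx <= 0] <- 1
          b <- b / rep(mx, each = nrow(b)); bsc <- bsc + log(mx)
          maway <- M[[z]][[ct_slot(ct, z, node)]]
          scaway <- SC[[z]][[ct_slot(ct, z, node)]]
          sc <- score_target(msub, scsub, tsub, b, bsc, tz / 2, maway, scaway, tz / 2)
          cands[[length(cands) + 1L]] <-
            list(r = r, p = p, x = node, y = z, gain = sc - cur_loglik)
          if (z > ct$ntip && st$depth < radius) {
            queue[[length(queue) + 1L]] <- list(prev = node, node = z, B = b,
                                                Bsc = bsc, tprev = tz,
                                                depth = st$depth + 1L)
          }
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  cands[order(-vapply(cands, `[[`, 0, "gain"))]
}

# one SPR improvement phase: scan, then greedily apply exact-improving
# candidates (re-validated against the current tree), rescanning until no
# candidate improves the exact log-likelihood by > eps.
spr_rounds <- function(ct, tips, model, weights, radius, eps = 0.01,
                       max_moves = 100) {
  cur <- loglik_inward(ct, tips, model, weights)$loglik
  moves <- 0L
  if (radius < 1 || ct$ntip < 4) return(list(ct = ct, loglik = cur, moves = moves))
  repeat {
    cache <- compute_messages(ct, tips, model)
    cands <- spr_scan(ct, cache, model, weights, cur, radius)
    if (!length(cands)) break
    applied <- FALSE
    tried <- 0L
    pool <- list()                       # best exactly-scored non-improving moves
    for (cand in cands) {
      # lazy gains under-score moves whose branch lengths need adjusting,
      # so the top candidates are exactly evaluated even when their lazy
      # gain is not positive
      if (cand$gain <= eps && tried >= 15L) next
      ct2 <- try(ct_spr(ct, cand$r, cand$p, cand$x, cand$y), silent = TRUE)
      if (inherits(ct2, "try-error")) next
      tried <- tried + 1L
      ll2 <- loglik_inward(ct2, tips, model, weights)$loglik
      if (!is.finite(ll2)) next
      if (ll2 > cur + eps) {
        ct <- ct2; cur <- ll2
        applied <- TRUE; moves <- moves + 1L
        if (moves >= max_moves) break
      } else if (!applied) {
        pool[[length(pool) + 1L]] <- list(ct = ct2, ll = ll2)
      }
    }
    if (!applied && length(pool)) {
      # rescue: refit branch lengths on the best near-misses
      ord <- order(-vapply(pool, `[[`, 0, "ll"))
      for (i in utils::head(ord, 2L)) {
        bo <- opt_branch_ct(pool[[i]]$ct, tips, model, weights,
                            eps = eps, max_sweeps = 2)
        if (is.finite(bo$loglik) && bo$loglik > cur + eps) {
          ct <- bo$ct; cur <- bo$loglik
          applied <- TRUE; moves <- moves + 1L
          break
        }
      }
    }
    if (!applied || moves >= max_moves) break
    # re-tune branch lengths after accepting moves
    bo <- opt_branch_ct(ct, tips, model, weights, eps = eps, max_sweeps = 2)
    ct <- bo$ct; cur <- bo$loglik
  }
  list(ct = ct, loglik = cur, moves = moves)
}
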