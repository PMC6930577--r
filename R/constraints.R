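# Constraint tables and their compilation into the flat arrays the engine
# consumes. The native representation is tidy: one tibble per constraint
# class, one row per experimental datum.

#' Constraint table constructors
#'
#' Build validated constraint tibbles in the package's native dialects.
#' `rdc_table()`: `class` is `"one-bond"`, `"long-range"` or `"methyl"`;
#' for a methyl datum `i` is the carbon and `j`, `h2`, `h3` its three
#' protons. `noe_table()`: a methyl partner is given as protons `j`, `h2`,
#' `h3` (the identical constraint is applied to each). `j_table()`: `chi`
#' and `xi` are comma-separated substituent descriptors.
#'
#' @param id datum identifier.
#' @param class RDC class tag.
#' @param i,j,h2,h3,k,l 1-based atom indices (`NA` where unused).
#' @param d_exp,target,j_exp experimental values (Hz, A, Hz).
#' @param error experimental error (> 0), same units.
#' @param delta tanh width; defaults: 0.5 Hz (RDC), 0.25 A (NOE),
#'   0.5 Hz (3J).
#' @param d_stat static splitting, Hz; `NA` uses [d_stat_default()] for
#'   one-bond/methyl classes or the frozen distance-derived value for
#'   long-range H-H.
#' @param chi,xi comma-separated electronegativity differences and
#'   orientation signs.
#' @param param_set Karplus parameter set name, see [haasnoot_params()].
#' @return a tibble.
#' @name constraint-tables
NULL

#' @rdname constraint-tables
#' @export
rdc_table <- function(id, class, i, j, h2 = NA_integer_, h3 = NA_integer_,
                      d_exp, error, delta = 0.5, d_stat = NA_real_) {
  out <- tibble::tibble(id = as.character(id), class = class,
                        i = as.integer(i), j = as.integer(j),
                        h2 = as.integer(h2), h3 = as.integer(h3),
                        d_exp = d_exp, error = error, delta = delta,
                        d_stat = d_stat)
  stopifnot(all(out$class %in% c("one-bond", "long-range", "methyl")),
            all(out$error > 0), all(out$delta > 0))
  out
}

#' @rdname constraint-tables
#' @export
noe_table <- function(id, i, j, h2 = NA_integer_, h3 = NA_integer_,
                      target, error, delta = 0.25) {
  out <- tibble::tibble(id = as.character(id), i = as.integer(i),
                        j = as.integer(j), h2 = as.integer(h2),
                        h3 = as.integer(h3), target = target, error = error,
                        delta = delta)
  stopifnot(all(out$target > 0), all(out$error > 0), all(out$delta > 0))
  out
}

#' @rdname constraint-tables
#' @export
j_table <- function(id, i, j, k, l, j_exp, error, delta = 0.5,
                    chi = "", xi = "", param_set = "hla2") {
  out <- tibble::tibble(id = as.character(id), i = as.integer(i),
                        j = as.integer(j), k = as.integer(k),
                        l = as.integer(l), j_exp = j_exp, error = error,
                        delta = delta, chi = as.character(chi),
                        xi = as.character(xi), param_set = param_set)
  stopifnot(all(out$error > 0), all(out$delta > 0))
  out
}

parse_numlist <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ",")[[1]])
}

# Compile the tidy tables into 0-based arrays; freeze long-range D_stat from
# the starting geometry; attach bookkeeping used to map results back.
compile_constraints <- function(system, constraints, config, conf) {
  n <- nrow(system$atoms)
  cons <- empty_cons()
  rdc <- constraints$rdc %||% rdc_table(character(0), character(0),
                                        integer(0), integer(0),
                                        d_exp = numeric(0), error = numeric(0))
  noe <- constraints$noe %||% noe_table(character(0), integer(0), integer(0),
                                        target = numeric(0), error = numeric(0))
  jt <- constraints$j %||% j_table(character(0), integer(0), integer(0),
                                   integer(0), integer(0),
                                   j_exp = numeric(0), error = numeric(0))
  xyz <- as_xyz(conf)
  chk <- function(ix, what) {
    ix <- ix[!is.na(ix)]
    if (any(ix < 1 | ix > n)) {
      stop(what, " constraint references missing atom ",
           paste(ix[ix < 1 | ix > n], collapse = ", "))
    }
  }
  chk(unlist(rdc[c("i", "j", "h2", "h3")]), "RDC")
  chk(unlist(noe[c("i", "j", "h2", "h3")]), "NOE")
  chk(unlist(jt[c("i", "j", "k", "l")]), "3J")

  nr <- nrow(rdc)
  if (nr) {
    idx <- matrix(-1L, nr, 6)
    np <- integer(nr)
    dmax <- numeric(nr)
    for (r in seq_len(nr)) {
      if (rdc$class[r] == "methyl") {
        hs <- c(rdc$j[r], rdc$h2[r], rdc$h3[r])
        if (anyNA(hs)) stop("methyl RDC ", rdc$id[r], " needs three protons")
        idx[r, ] <- as.integer(c(rbind(rdc$i[r], hs))) - 1L
        np[r] <- 3L
        ds <- if (is.na(rdc$d_stat[r])) d_stat_default("ch_sp3") else rdc$d_stat[r]
      } else {
        idx[r, 1:2] <- c(rdc$i[r], rdc$j[r]) - 1L
        np[r] <- 1L
        ds <- rdc$d_stat[r]
        if (is.na(ds)) {
          ds <- if (rdc$class[r] == "one-bond") d_stat_default("ch_sp3") else {
            rr <- sqrt(sum((xyz[rdc$i[r], ] - xyz[rdc$j[r], ])^2))
            .hh_dipolar_prefactor * 1000 / rr^3   # frozen at configuration time
          }
        }
      }
      dmax[r] <- config$s_am * ds
    }
    if (any(abs(rdc$d_exp) > abs(dmax))) {
      warning("experimental RDC exceeds s_am * D_stat for: ",
              paste(rdc$id[abs(rdc$d_exp) > abs(dmax)], collapse = ", "))
    }
    cons$rdc_idx <- idx; cons$rdc_np <- np
    cons$rdc_dmax <- dmax; cons$rdc_dexp <- rdc$d_exp
    cons$rdc_dD <- ifelse(is.na(rdc$delta), 0.5, rdc$delta)
    rdc$dmax <- dmax
    rdc$type <- ifelse(rdc$class == "long-range", "nD", "1D")
  } else {
    rdc$dmax <- numeric(0); rdc$type <- character(0)
  }

  ni <- nrow(noe)
  pr_i <- integer(0); pr_j <- integer(0); pr_d <- character(0)
  pr_rexp <- numeric(0); pr_dr <- numeric(0)
  if (ni) {
    for (p in seq_len(ni)) {
      partners <- c(noe$j[p], noe$h2[p], noe$h3[p])
      partners <- partners[!is.na(partners)]
      for (q in partners) {
        pr_i <- c(pr_i, noe$i[p]); pr_j <- c(pr_j, q); pr_d <- c(pr_d, noe$id[p])
        pr_rexp <- c(pr_rexp, noe$target[p])
        pr_dr <- c(pr_dr, ifelse(is.na(noe$delta[p]), 0.25, noe$delta[p]))
      }
    }
    cons$noe_idx <- cbind(pr_i, pr_j) - 1L
    cons$noe_rexp <- pr_rexp; cons$noe_dr <- pr_dr
  }
  noe_pairs <- tibble::tibble(i = pr_i, j = pr_j,
                              datum = factor(pr_d, levels = unique(noe$id)))

  nj <- nrow(jt)
  if (nj) {
    cons$j_idx <- cbind(jt$i, jt$j, jt$k, jt$l) - 1L
    cons$j_jexp <- jt$j_exp
    cons$j_dD <- ifelse(is.na(jt$delta), 0.5, jt$delta)
    P <- t(vapply(jt$param_set, function(s) {
      p <- as.numeric(haasnoot_params(s)); p[6] <- deg2rad(p[6]); p
    }, numeric(6)))
    cons$j_P <- matrix(P, nj, 6)
    chi <- matrix(0, nj, 4); xi <- matrix(1, nj, 4); ns <- integer(nj)
    for (t_ in seq_len(nj)) {
      cv <- parse_numlist(jt$chi[t_]); xv <- parse_numlist(jt$xi[t_])
      if (length(cv) != length(xv)) {
        stop("3J ", jt$id[t_], ": chi and xi descriptor counts differ")
      }
      if (length(xv) && any(abs(xv) != 1)) {
        stop("3J ", jt$id[t_], ": xi signs must be +-1")
      }
      ns[t_] <- length(cv)
      if (ns[t_] > 4) stop("3J ", jt$id[t_], ": at most 4 substituents")
      if (ns[t_]) { chi[t_, seq_len(ns[t_])] <- cv; xi[t_, seq_len(ns[t_])] <- xv }
    }
    cons$j_chi <- chi; cons$j_xi <- xi; cons$j_ns <- ns
  }

  list(cons = cons,
       book = list(rdc = rdc, noe = noe, noe_pairs = noe_pairs, j = jt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
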