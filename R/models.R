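.nuc_states <- c("A", "C", "G", "T")
.nuc_pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Build a reversible substitution model
#'
#' Constructs a time-reversible rate matrix `Q` with `q_ij = s_ij * pi_j`
#' (i != j), a rate-category mixture, and an invariant-site proportion.
#' `Q` is scaled so that the expected substitution rate at equilibrium,
#' averaged over rate categories and the invariant class, equals 1, i.e.
#' branch lengths are in substitutions per site: the rate matrix itself is
#' normalized to `-sum(pi_i q_ii) = 1` and the category rates are rescaled
#' so `(1 - p_inv) * sum(w_i r_i) = 1`.
#'
#' Named patterns: `JC69` (equal everything), `K80`/`HKY85` (transition/
#' transversion ratio `kappa`; K80 forces equal frequencies), `TIM3` (GTR
#' with the ties AC = CG and AT = GT), `GTR` (six free exchangeabilities),
#' and `JC2` (two-state equal-rate, equal-frequency model used for gap
#' presence/absence).
#'
#' @param name Model pattern, one of `"JC69"`, `"K80"`, `"HKY85"`, `"TIM3"`,
#'   `"GTR"`, `"JC2"`.
#' @param frequencies Stationary frequencies (simplex over the states);
#'   ignored where the pattern fixes them.
#' @param exchangeabilities Named vector over `AC, AG, AT, CG, CT, GT` (ties
#'   enforced for TIM3); ignored for JC69/K80/HKY85/JC2.
#' @param kappa Transition/transversion ratio for K80/HKY85.
#' @param rates,weights Rate-category mixture (free rates and weights, e.g.
#'   a 4-category FreeRate mixture); defaults to a single unit-rate class.
#' @param p_inv Invariant-site proportion in `[0, 1)`.
#' @return An object of class `subst_model` with the normalized `Q`, the
#'   eigendecomposition used by [transition_matrix()], frequencies, rescaled
#'   category rates/weights and `p_inv`.
#' @export
build_model <- function(name, frequencies = NULL, exchangeabilities = NULL,
                        kappa = NULL, rates = 1, weights = 1, p_inv = 0) {
  name <- match.arg(name, c("JC69", "K80", "HKY85", "TIM3", "GTR", "JC2"))
  if (name == "JC2") {
    states <- c("0", "1")
    freqs <- c(0.5, 0.5)
    S <- matrix(c(0, 1, 1, 0), 2L, 2L)
  } else {
    states <- .nuc_states
    freqs <- switch(name,
                    JC69 = , K80 = rep(0.25, 4L),
                    {
                      if (is.null(frequencies))
                        stop(name, " requires stationary frequencies")
                      frequencies
                    })
    ex <- switch(name,
                 JC69 = stats::setNames(rep(1, 6L), .nuc_pairs),
                 K80 = , HKY85 = {
                   if (is.null(kappa)) stop(name, " requires kappa")
                   stats::setNames(c(1, kappa, 1, 1, kappa, 1), .nuc_pairs)
                 },
                 TIM3 = {
                   e <- .full_exchangeabilities(exchangeabilities,
                                                required = c("AC", "AG",
                                                             "AT", "CT"))
                   e["CG"] <- e["AC"]
                   e["GT"] <- e["AT"]
                   e
                 },
                 GTR = .full_exchangeabilities(exchangeabilities,
                                               required = .nuc_pairs))
    if (any(!is.finite(ex)) || any(ex <= 0))
      stop("exchangeabilities must be positive and finite ",
           "(a zero rate breaks irreducibility)")
    S <- matrix(0, 4L, 4L, dimnames = list(states, states))
    for (p in .nuc_pairs) {
      i <- substr(p, 1L, 1L); j <- substr(p, 2L, 2L)
      S[i, j] <- S[j, i] <- ex[[p]]
    }
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != length(states) || any(!is.finite(freqs)) ||
      any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("frequencies must be a strictly positive simplex over ",
         length(states), " states")
  freqs <- freqs / sum(freqs)
  names(freqs) <- states
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("category rates must be positive")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("category weights must be a positive simplex")
  weights <- weights / sum(weights)
  if (length(rates) != length(weights))
    stop("rates and weights must have equal length")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")

  Q <- S * rep(freqs, each = length(states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  rates <- rates / ((1 - p_inv) * sum(weights * rates))

  # symmetric eigendecomposition of D^{1/2} Q D^{-1/2}; reversibility
  # guarantees a real spectrum, so P(t) is exact up to eigen precision
  sq <- sqrt(freqs)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / sq
  Uinv <- t(eig$vectors) * rep(sq, each = length(states))

  structure(list(name = name, states = states, freqs = freqs, Q = Q,
                 rates = rates, weights = weights, p_inv = p_inv,
                 eig_values = eig$values, eig_U = U, eig_Uinv = Uinv),
            class = "subst_model")
}

.full_exchangeabilities <- function(ex, required) {
  if (is.null(ex)) stop("exchangeabilities required: ",
                        paste(required, collapse = ", "))
  if (is.null(names(ex))) {
    if (length(ex) != length(required))
      stop("unnamed exchangeabilities must have length ", length(required))
    names(ex) <- required
  }
  missing_p <- setdiff(required, names(ex))
  if (length(missing_p))
    stop("missing exchangeabilities: ", paste(missing_p, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, 6L), .nuc_pairs)
  out[names(ex)] <- ex
  out
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> ", x$name, ": ", length(x$states), " states, ",
      length(x$rates), " rate categories, p_inv = ", x$p_inv, "\n", sep = "")
  invisible(x)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q * r * t)`, computed from the symmetric eigendecomposition
#' stored in the model. Rows sum to 1 within 1e-12 and `P(0)` is the
#' identity.
#'
#' @param model A `subst_model`.
#' @param t Branch length in substitutions/site (non-negative).
#' @param r Rate-category multiplier (positive, default 1).
#' @return Stochastic matrix over the model states.
#' @export
transition_matrix <- function(model, t, r = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (!is.finite(r) || r <= 0) stop("category rate must be positive")
  P <- model$eig_U %*% (exp(model$eig_values * r * t) * model$eig_Uinv)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(model$states, model$states)
  P
}
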