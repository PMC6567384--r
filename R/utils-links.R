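## Link functions. Binomial probabilities use the logit; each age class's
## (poach, other, survive) triple uses the multinomial logit with survival as
## the reference category, which enforces mPoach + mOther <= 1 for any finite
## linear predictors.

logit <- function(p) stats::qlogis(p)
invLogit <- function(x) stats::plogis(x)

## (etaP, etaO) -> (mP, mO); reference category = survive
mlogitInv <- function(etaP, etaO) {
  ## numerically safe softmax over (etaP, etaO, 0)
  m <- pmax(etaP, etaO, 0)
  eP <- exp(etaP - m); eO <- exp(etaO - m); e0 <- exp(-m)
  s <- eP + eO + e0
  cbind(poach = eP / s, other = eO / s)
}

## inverse of mlogitInv for probabilities strictly inside the simplex
mlogitLink <- function(mP, mO) {
  s <- 1 - mP - mO
  cbind(etaP = log(mP / s), etaO = log(mO / s))
}

## clamp probabilities away from 0/1 before taking a link
.clampP <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)
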