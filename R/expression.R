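## Exact symbolic expansion of a trained network.
##
## Multiplication units are expanded into monomials, division units are
## kept as rational terms with explicit numerator / denominator
## polynomials, like monomials are combined by summing coefficients.  The
## resulting expression evaluates identically (double precision) to the
## network forward pass away from the division safeguard region.

## ---- sparse multivariate polynomials ------------------------------------

# A polynomial is a named list keyed by canonical monomial string; each
# element holds the coefficient and the named integer exponent vector.
mono_key <- function(pow) {
  pow <- pow[pow != 0]
  if (length(pow) == 0) return("1")
  pow <- pow[order(names(pow))]
  paste(ifelse(pow > 1, paste0(names(pow), "^", pow), names(pow)),
        collapse = "*")
}

poly_zero <- function() structure(list(), class = "fp_poly")

poly_const <- function(c) {
  if (c == 0) return(poly_zero())
  structure(list(`1` = list(coef = c, pow = integer(0))), class = "fp_poly")
}

poly_var <- function(name, deg = 1L) {
  pow <- stats::setNames(as.integer(deg), name)
  structure(stats::setNames(list(list(coef = 1, pow = pow)), mono_key(pow)),
            class = "fp_poly")
}

poly_add <- function(p, q) {
  for (k in names(q)) {
    if (is.null(p[[k]])) p[[k]] <- q[[k]]
    else p[[k]]$coef <- p[[k]]$coef + q[[k]]$coef
  }
  poly_clean(p)
}

poly_scale <- function(p, a) {
  if (a == 0) return(poly_zero())
  for (k in names(p)) p[[k]]$coef <- p[[k]]$coef * a
  p
}

poly_mul <- function(p, q) {
  out <- poly_zero()
  for (k1 in names(p)) for (k2 in names(q)) {
    pow <- pow_add(p[[k1]]$pow, q[[k2]]$pow)
    key <- mono_key(pow)
    c12 <- p[[k1]]$coef * q[[k2]]$coef
    if (is.null(out[[key]])) out[[key]] <- list(coef = c12, pow = pow)
    else out[[key]]$coef <- out[[key]]$coef + c12
  }
  poly_clean(out)
}

pow_add <- function(a, b) {
  vars <- union(names(a), names(b))
  out <- stats::setNames(integer(length(vars)), vars)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

poly_clean <- function(p) {
  keep <- vapply(p, function(m) m$coef != 0, TRUE)
  structure(p[keep], class = "fp_poly")
}

poly_prune <- function(p, tol) {
  keep <- vapply(p, function(m) abs(m$coef) >= tol, TRUE)
  structure(p[keep], class = "fp_poly")
}

poly_eval <- function(p, env) {
  out <- 0
  for (m in p) {
    v <- m$coef
    for (var in names(m$pow)) v <- v * env[[var]]^m$pow[[var]]
    out <- out + v
  }
  out
}

poly_vars <- function(p) {
  unique(unlist(lapply(p, function(m) names(m$pow))))
}

poly_deg <- function(p, var) {
  if (length(p) == 0) return(-Inf)
  max(vapply(p, function(m) {
    d <- m$pow[var]; if (is.na(d)) 0L else d
  }, 0L))
}

poly_is_zero <- function(p) length(p) == 0

# Canonical serialization (used to merge rational terms sharing a
# denominator).
poly_key <- function(p) {
  if (length(p) == 0) return("0")
  ks <- sort(names(p))
  paste(vapply(ks, function(k) sprintf("%s:%.15g", k, p[[k]]$coef), ""),
        collapse = "+")
}

format_poly <- function(p, digits = 4) {
  if (length(p) == 0) return("0")
  ks <- names(p)[order(nchar(names(p)), names(p))]
  pieces <- vapply(ks, function(k) {
    cf <- signif(p[[k]]$coef, digits)
    if (k == "1") sprintf("%g", cf)
    else if (cf == 1) k
    else if (cf == -1) paste0("-", k)
    else sprintf("%g*%s", cf, k)
  }, "")
  out <- pieces[1]
  for (s in pieces[-1])
    out <- if (startsWith(s, "-")) paste0(out, " - ", substring(s, 2))
           else paste0(out, " + ", s)
  out
}

# Long division of `num` by a univariate `den` (variable `var`): returns
# quotient polynomial and proper remainder.
poly_divmod <- function(num, den, var) {
  dd <- poly_deg(den, var)
  stopifnot(is.finite(dd), all(vapply(den, function(m)
    all(names(m$pow) == var), TRUE)))
  lead_key <- mono_key(stats::setNames(as.integer(dd), var))
  clead <- den[[lead_key]]$coef
  quo <- poly_zero()
  rem <- num
  repeat {
    dn <- poly_deg(rem, var)
    if (!is.finite(dn) || dn < dd) break
    # leading coefficient of rem in var (a polynomial in the other vars)
    lead <- poly_zero()
    for (m in rem) {
      d <- m$pow[var]; if (is.na(d)) d <- 0L
      if (d == dn) {
        pw <- m$pow[names(m$pow) != var]
        key <- mono_key(pw)
        lead[[key]] <- list(coef = m$coef, pow = pw)
      }
    }
    class(lead) <- "fp_poly"
    piece <- poly_scale(poly_mul(lead, poly_var(var, dn - dd)), 1 / clead)
    if (dn == dd) piece <- poly_scale(lead, 1 / clead)
    quo <- poly_add(quo, piece)
    rem <- poly_add(rem, poly_scale(poly_mul(piece, den), -1))
  }
  list(quotient = quo, remainder = rem)
}

## ---- sums of polynomial and rational parts ------------------------------

val_poly <- function(p) list(list(type = "poly", p = p))

val_scale <- function(v, a) {
  if (a == 0) return(list())
  lapply(v, function(part) {
    if (part$type == "poly") list(type = "poly", p = poly_scale(part$p, a))
    else list(type = "ratio", num = poly_scale(part$num, a), den = part$den)
  })
}

val_add <- function(v1, v2) {
  ppoly <- poly_zero()
  ratios <- list()
  for (part in c(v1, v2)) {
    if (part$type == "poly") ppoly <- poly_add(ppoly, part$p)
    else {
      key <- poly_key(part$den)
      if (is.null(ratios[[key]])) ratios[[key]] <- part
      else ratios[[key]]$num <- poly_add(ratios[[key]]$num, part$num)
    }
  }
  out <- list()
  if (!poly_is_zero(ppoly)) out <- val_poly(ppoly)
  c(out, unname(ratios))
}

val_mul <- function(v1, v2) {
  out <- list()
  for (a in v1) for (b in v2) {
    part <- if (a$type == "poly" && b$type == "poly")
      list(type = "poly", p = poly_mul(a$p, b$p))
    else if (a$type == "poly")
      list(type = "ratio", num = poly_mul(a$p, b$num), den = b$den)
    else if (b$type == "poly")
      list(type = "ratio", num = poly_mul(a$num, b$p), den = a$den)
    else
      list(type = "ratio", num = poly_mul(a$num, b$num),
           den = poly_mul(a$den, b$den))
    out <- val_add(out, list(part))
  }
  out
}

val_div <- function(v1, v2) {
  if (length(v1) == 0) return(list())   # zero numerator: the unit is zero
  if (length(v2) == 0)
    stop("division by an identically-zero denominator")
  if (length(v2) != 1 || v2[[1]]$type != "poly")
    stop("division by a nested rational expression is not supported")
  den <- v2[[1]]$p
  if (poly_is_zero(den)) stop("division by an identically-zero denominator")
  lapply(v1, function(part) {
    if (part$type == "poly")
      list(type = "ratio", num = part$p, den = den)
    else
      list(type = "ratio", num = part$num, den = poly_mul(part$den, den))
  })
}

## ---- symbolic model ------------------------------------------------------

# A term of a symbolic model: a coefficient times a product of base symbols
# (u, v, ua = u^alpha, I, derivative channels) given by `pow`, and
# optionally a rational factor num/den (den univariate).
fp_term <- function(coef, pow = integer(0), ratio = NULL) {
  pow <- pow[pow != 0]
  list(coef = coef, pow = pow, ratio = ratio)
}

#' @export
print.fp_expression <- function(x, ...) {
  cat(format_expression(x), "\n")
  invisible(x)
}

#' Format a symbolic model as an equation string
#' @param x an `fp_expression`.
#' @param digits significant digits.
#' @return a character string.
#' @export
format_expression <- function(x, digits = 4) {
  if (length(x$terms) == 0) return("0")
  pieces <- vapply(x$terms, function(tm) {
    sym <- mono_key(tm$pow)
    cf <- signif(tm$coef, digits)
    base <- if (is.null(tm$ratio)) {
      if (sym == "1") sprintf("%g", cf)
      else if (cf == 1) sym
      else if (cf == -1) paste0("-", sym)
      else sprintf("%g*%s", cf, sym)
    } else {
      frac <- sprintf("(%s)/(%s)", format_poly(tm$ratio$num, digits),
                      format_poly(tm$ratio$den, digits))
      pre <- if (sym == "1") sprintf("%g*", cf) else sprintf("%g*%s*", cf, sym)
      paste0(pre, frac)
    }
    base
  }, "")
  out <- pieces[1]
  for (s in pieces[-1])
    out <- if (startsWith(s, "-")) paste0(out, " - ", substring(s, 2))
           else paste0(out, " + ", s)
  if (!is.null(x$alpha) && length(x$alpha) == 1 && !is.na(x$alpha))
    out <- gsub("ua", sprintf("u^%.4g", x$alpha), out, fixed = TRUE)
  out
}

#' Expand a trained network into an explicit symbolic model
#'
#' Multiplication units are expanded into monomials, division units kept as
#' rational terms (numerator / denominator polynomials), like monomials
#' combined, and rational terms sharing a denominator merged.  Each rational
#' term is normalized so its denominator is monic in its leading variable
#' and its numerator's largest coefficient is folded into the term
#' coefficient.  Terms with `|coefficient| < prune_tol` are dropped.
#'
#' Numerically evaluating the result reproduces [symnet_forward()] to
#' machine precision wherever no division denominator falls inside the
#' safeguard clamp.
#'
#' @param net an [fp_symnet()].
#' @param prune_tol display pruning tolerance (default `1e-4`).
#' @param alpha numeric exponent recorded on the expression (for libraries
#'   with a `ua` channel).
#' @return an object of class `fp_expression`: `list(terms, alpha)`.
#' @export
symnet_to_expression <- function(net, prune_tol = 1e-4, alpha = NA_real_) {
  vals <- lapply(net$channels, function(nm) val_poly(channel_poly(nm)))
  k <- length(net$units)
  for (i in seq_len(k)) {
    Wi <- net$W[[i]]; bi <- net$b[[i]]
    eta <- if (bi[1] != 0) val_poly(poly_const(bi[1])) else list()
    xi  <- if (bi[2] != 0) val_poly(poly_const(bi[2])) else list()
    for (c in seq_len(ncol(Wi))) {
      if (Wi[1, c] != 0) eta <- val_add(eta, val_scale(vals[[c]], Wi[1, c]))
      if (Wi[2, c] != 0) xi  <- val_add(xi,  val_scale(vals[[c]], Wi[2, c]))
    }
    vals[[length(vals) + 1]] <-
      if (net$units[i] == "mul") val_mul(eta, xi) else val_div(eta, xi)
  }
  out <- if (net$bout != 0) val_poly(poly_const(net$bout)) else list()
  for (c in seq_along(vals))
    if (net$Wout[c] != 0) out <- val_add(out, val_scale(vals[[c]], net$Wout[c]))
  value_to_expression(out, prune_tol, alpha)
}

value_to_expression <- function(val, prune_tol, alpha = NA_real_) {
  terms <- list()
  for (part in val) {
    if (part$type == "poly") {
      for (m in part$p)
        if (abs(m$coef) >= prune_tol)
          terms[[length(terms) + 1]] <- fp_term(m$coef, m$pow)
    } else {
      tm <- normalize_ratio(part$num, part$den)
      if (abs(tm$coef) >= prune_tol) terms[[length(terms) + 1]] <- tm
    }
  }
  structure(list(terms = terms, alpha = alpha), class = "fp_expression")
}

# Fold numerator scale into the coefficient and make the denominator monic
# in its leading variable.
normalize_ratio <- function(num, den) {
  dvars <- poly_vars(den)
  var <- if (length(dvars) == 0) NA_character_ else
    dvars[which.max(vapply(dvars, function(v) poly_deg(den, v), 0L))]
  s_den <- 1
  if (!is.na(var)) {
    dd <- poly_deg(den, var)
    lead_key <- mono_key(stats::setNames(as.integer(dd), var))
    if (!is.null(den[[lead_key]])) s_den <- den[[lead_key]]$coef
  }
  s_num <- if (length(num) == 0) 1 else
    max(abs(vapply(num, function(m) m$coef, 0)))
  s_num <- s_num * sign(num_lead_sign(num))
  fp_term(coef = s_num / s_den,
          ratio = list(num = poly_scale(num, 1 / s_num),
                       den = poly_scale(den, 1 / s_den),
                       var = var))
}

num_lead_sign <- function(num) {
  if (length(num) == 0) return(1)
  cfs <- vapply(num, function(m) m$coef, 0)
  s <- sign(cfs[which.max(abs(cfs))])
  if (s == 0) 1 else s
}

#' Evaluate a symbolic model on field values
#'
#' @param expr an `fp_expression`.
#' @param env named list of arrays: base fields `u`, `v` plus whatever
#'   symbols the expression uses (`ua`, `I`, `uxx`, ...).
#' @return numeric array.
#' @export
expression_eval <- function(expr, env) {
  out <- 0
  for (tm in expr$terms) out <- out + term_eval_with_coef(tm, env)
  out
}

term_eval_with_coef <- function(tm, env) tm$coef * term_eval(tm, env)

# Term column without its coefficient.
term_eval <- function(tm, env) {
  v <- 1
  for (var in names(tm$pow)) v <- v * env[[var]]^tm$pow[[var]]
  if (!is.null(tm$ratio))
    v <- v * poly_eval(tm$ratio$num, env) / poly_eval(tm$ratio$den, env)
  v
}

term_label <- function(tm) {
  sym <- mono_key(tm$pow)
  if (is.null(tm$ratio)) sym
  else paste0(if (sym == "1") "" else paste0(sym, "*"),
              "(", format_poly(tm$ratio$num), ")/(",
              format_poly(tm$ratio$den), ")")
}

# Coefficient of a plain monomial term in an expression (0 when absent).
#' Extract the coefficient of a monomial term
#'
#' @param expr an `fp_expression`.
#' @param symbol monomial label such as `"u"`, `"uxx"`, `"u^2"`, `"u*v"`,
#'   or `"1"` for the constant term.
#' @return the coefficient (0 if the term is absent).
#' @export
coef_of <- function(expr, symbol) {
  for (tm in expr$terms) {
    if (is.null(tm$ratio) && mono_key(tm$pow) == symbol) return(tm$coef)
  }
  0
}

# Rational terms of an expression.
ratio_terms <- function(expr) {
  Filter(function(tm) !is.null(tm$ratio), expr$terms)
}
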