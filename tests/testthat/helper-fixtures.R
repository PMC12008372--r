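# Small shared fixtures, built in code at test time.

mops <- mops_phase_space()
mops_yield <- mops_phase_space(glucose_variable = TRUE)

# a tiny 3-component space with round numbers for arithmetic-level checks
tiny_space <- phase_space(data.frame(
  name = c("A", "B", "C"),
  base = c(10, 50, 1),
  lower = c(1, 5, 1),
  upper = c(100, 500, 1),
  solubility = c(1000, 5000, 10),
  fixed = c(FALSE, FALSE, TRUE),
  unit = "mM"
))

# deterministic linear toy model exposing the predict(mean, var) contract
constant_var_model <- function(beta0, beta, var = 0) {
  structure(list(beta0 = beta0, beta = beta, var = var),
            class = "toy_linear_model")
}

predict.toy_linear_model <- function(object, newdata, ...) {
  X <- rbind(newdata)
  list(mean = object$beta0 + as.vector(X %*% object$beta),
       var = rep(object$var, nrow(X)))
}

# registered so S3 dispatch works inside package code calling predict()
.S3method("predict", "toy_linear_model", predict.toy_linear_model)

# concave quadratic mean surface with zero variance, peaked at x0
quad_test_model <- function(x0) {
  structure(list(x0 = x0), class = "quad_test_model")
}

predict.quad_test_model <- function(object, newdata, ...) {
  X <- rbind(newdata)
  list(mean = -rowSums(sweep(X, 2, object$x0)^2), var = rep(0, nrow(X)))
}

.S3method("predict", "quad_test_model", predict.quad_test_model)
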