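# cached model fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

tiny_model <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- build_model(preset_spec("tiny"))
  .fixtures$tiny
}

coarse_model <- function() {
  if (is.null(.fixtures$coarse))
    .fixtures$coarse <- build_model(preset_spec("coarse"))
  .fixtures$coarse
}

full_model <- function() {
  if (is.null(.fixtures$full))
    .fixtures$full <- build_model(preset_spec("full"))
  .fixtures$full
}

# dense complex quadratic form oracle for damping power
dense_loss_oracle <- function(model, u, omega) {
  C <- as.matrix(model$mats$C)
  0.5 * omega^2 * Re(Conj(u) %*% C %*% u)[1, 1]
}
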