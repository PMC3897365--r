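rel_err <- function(x, ref) abs(x / ref - 1)

# dormancy-regime parameter set: 30x inhibitor production with the local
# inhibition coefficients rescaled proportionally through the diffusion
# formula
dormancy_parameters <- function(pars = default_parameters(),
                                p = 2.5e-4) {
  pp <- unclass(pars)
  pp$p <- p
  dnew <- derive_local_inhibition(e = pars$e, Vd = pars$Vd, p = p,
                                  D2 = pars$D2)
  pp$d <- dnew
  pp$d_p <- dnew
  do.call(model_parameters, pp)
}
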