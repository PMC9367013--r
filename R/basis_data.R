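# Built-in Gaussian basis sets (standard published exponents and contraction
# coefficients). Each element maps to a list of shells; "sp" shells are stored
# as separate s and p shells sharing exponents. Exponents in Bohr^-2.

.STO3G_S <- c(0.1543289673, 0.5353281423, 0.4446345422)
.STO3G_SP_S <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.STO3G_SP_P <- c(0.1559162750, 0.6076837186, 0.3919573931)

.BASIS_LIBRARY <- list(
  "sto-3g" = list(
    H = list(list(l = 0, exps = c(3.425250914, 0.6239137298, 0.1688554040),
                  coefs = .STO3G_S)),
    He = list(list(l = 0, exps = c(6.362421394, 1.158922999, 0.3136497915),
                   coefs = .STO3G_S)),
    C = list(
      list(l = 0, exps = c(71.61683735, 13.04509632, 3.530512160), coefs = .STO3G_S),
      list(l = 0, exps = c(2.941249355, 0.6834830964, 0.2222899159), coefs = .STO3G_SP_S),
      list(l = 1, exps = c(2.941249355, 0.6834830964, 0.2222899159), coefs = .STO3G_SP_P)),
    N = list(
      list(l = 0, exps = c(99.10616896, 18.05231239, 4.885660238), coefs = .STO3G_S),
      list(l = 0, exps = c(3.780455879, 0.8784966449, 0.2857143744), coefs = .STO3G_SP_S),
      list(l = 1, exps = c(3.780455879, 0.8784966449, 0.2857143744), coefs = .STO3G_SP_P)),
    O = list(
      list(l = 0, exps = c(130.7093214, 23.80886605, 6.443608313), coefs = .STO3G_S),
      list(l = 0, exps = c(5.033151319, 1.169596125, 0.3803889600), coefs = .STO3G_SP_S),
      list(l = 1, exps = c(5.033151319, 1.169596125, 0.3803889600), coefs = .STO3G_SP_P)),
    F = list(
      list(l = 0, exps = c(166.6791340, 30.36081233, 8.216820672), coefs = .STO3G_S),
      list(l = 0, exps = c(6.464803249, 1.502281245, 0.4885884864), coefs = .STO3G_SP_S),
      list(l = 1, exps = c(6.464803249, 1.502281245, 0.4885884864), coefs = .STO3G_SP_P))
  ),
  "6-31g" = list(
    H = list(
      list(l = 0, exps = c(18.73113696, 2.825394365, 0.6401216923),
           coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = 0, exps = 0.1612777588, coefs = 1.0)),
    He = list(
      list(l = 0, exps = c(38.42163400, 5.778030000, 1.241774000),
           coefs = c(0.04013973935, 0.2612460970, 0.7931846246)),
      list(l = 0, exps = 0.2979640000, coefs = 1.0)),
    C = list(
      list(l = 0,
           exps = c(3047.524880, 457.3695180, 103.9486850, 29.21015530,
                    9.286662960, 3.163926960),
           coefs = c(0.001834737132, 0.01403732281, 0.06884262226,
                     0.2321844432, 0.4679413484, 0.3623119853)),
      list(l = 0, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(-0.1193324198, -0.1608541517, 1.143456438)),
      list(l = 1, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(0.06899906659, 0.3164239610, 0.7443082909)),
      list(l = 0, exps = 0.1687144782, coefs = 1.0),
      list(l = 1, exps = 0.1687144782, coefs = 1.0)),
    N = list(
      list(l = 0,
           exps = c(4173.511460, 627.4579110, 142.9020930, 40.23432930,
                    12.82021290, 4.390437010),
           coefs = c(0.001834772160, 0.01399462700, 0.06858655181,
                     0.2322408730, 0.4690699481, 0.3604551991)),
      list(l = 0, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(-0.1149611817, -0.1691174786, 1.145851947)),
      list(l = 1, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(0.06757974388, 0.3239072959, 0.7408951398)),
      list(l = 0, exps = 0.2120314975, coefs = 1.0),
      list(l = 1, exps = 0.2120314975, coefs = 1.0)),
    O = list(
      list(l = 0,
           exps = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                    16.89757040, 5.799635340),
           coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                     0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = 0, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
      list(l = 1, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = 0, exps = 0.2700058226, coefs = 1.0),
      list(l = 1, exps = 0.2700058226, coefs = 1.0)),
    F = list(
      list(l = 0,
           exps = c(7001.713090, 1051.366090, 239.2856900, 67.39744530,
                    21.51995730, 7.403101300),
           coefs = c(0.001819616901, 0.01391607961, 0.06840532453,
                     0.2331857601, 0.4712674392, 0.3566185462)),
      list(l = 0, exps = c(20.84795280, 4.808308340, 1.344069860),
           coefs = c(-0.1085069751, -0.1464516581, 1.128688581)),
      list(l = 1, exps = c(20.84795280, 4.808308340, 1.344069860),
           coefs = c(0.07162872424, 0.3459121027, 0.7224699564)),
      list(l = 0, exps = 0.3581513930, coefs = 1.0),
      list(l = 1, exps = 0.3581513930, coefs = 1.0))
  )
)

#' List the basis sets bundled with the package
#'
#' @return Character vector of basis-set names accepted by [build_basis()].
#' @export
available_bases <- function() names(.BASIS_LIBRARY)
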