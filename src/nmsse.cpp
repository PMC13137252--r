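// Trajectory propagation core for the perturbative time-local nonlinear
// NMSSE with dephasing-type coupling L = gamma * sigma_z, driven by a
// colored (Gaussian or shot-noise) process, with optional unitary kick
// events applied between steps.
//
// Conventions: hbar = 1, energies in eV, time in eV^-1. The state lives on
// the tensor space (electronic slow, Fock fast); Sz, Sy are the electronic
// Pauli operators lifted with identity on the mode.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

typedef std::complex<double> cplx;

namespace {

struct DriftCtx {
  const cx_mat& H;
  const cx_mat& Sz;
  const cx_mat& Sy;
  const cx_mat& Szz;   // Sz * Sz
  const cx_mat& Szy;   // Sz * Sy
  double gamma;
  double delta;
  double bracket_factor;  // 2 as printed, 1 with the typo switch
};

// Nonlinear drift evaluated at a *normalized* state.
// f = -i H psi + gamma * (Sz - <Sz>) psi * conj(ztilde)
//     - g0 * gamma^2 * [ (Sz - <Sz>) Sz - <(Sz - <Sz>) Sz> ] psi
//     + i g1 * gamma^2 * delta * [ (Sz - <Sz>) Sy - f2 <(Sz - <Sz>) Sy> ] psi
cx_vec drift_eval(const DriftCtx& c, const cx_vec& psi, cplx ztilde_conj,
                  cplx g0, cplx g1) {
  cx_vec szpsi = c.Sz * psi;
  cx_vec sypsi = c.Sy * psi;
  cx_vec szzpsi = c.Szz * psi;
  cx_vec szypsi = c.Szy * psi;
  double ez = std::real(cdot(psi, szpsi));
  double ey = std::real(cdot(psi, sypsi));
  cplx ezz = cdot(psi, szzpsi);
  cplx ezy = cdot(psi, szypsi);

  cx_vec f = cplx(0.0, -1.0) * (c.H * psi);
  f += c.gamma * ztilde_conj * (szpsi - ez * psi);
  double g2c = c.gamma * c.gamma;
  f -= g0 * g2c * (szzpsi - ez * szpsi - (ezz - ez * ez) * psi);
  f += cplx(0.0, 1.0) * g1 * g2c * c.delta *
       (szypsi - ez * sypsi - c.bracket_factor * (ezy - ez * ey) * psi);
  return f;
}

// trapezoidal memory convolution S_i = int_0^{t_i} alpha(t_i - s) c(s) ds
cplx shift_conv(const cx_vec& alpha, const std::vector<double>& chist,
                int i, double dt) {
  if (i == 0) return cplx(0.0, 0.0);
  cplx acc(0.0, 0.0);
  for (int j = 0; j <= i; ++j) {
    double w = (j == 0 || j == i) ? 0.5 : 1.0;
    acc += w * alpha(i - j) * chist[j];
  }
  return acc * dt;
}

struct KickSet {
  bool active;
  cx_mat V;          // eigenvectors of the mode quadrature b + b'
  vec E;             // eigenvalues
  double scale;
  int nf;            // mode dimension
  // U(a) = blockdiag( V e^{-i a s E} V^T , conj ), electronic slow index
  void apply(cx_vec& psi, double a) const {
    cx_vec ph = exp(cx_double(0.0, -1.0) * (a * scale) * conv_to<cx_vec>::from(E));
    cx_mat u = V * diagmat(ph) * V.t();
    psi.subvec(0, nf - 1) = u * psi.subvec(0, nf - 1);
    psi.subvec(nf, 2 * nf - 1) = conj(u) * psi.subvec(nf, 2 * nf - 1);
  }
};

struct StepResult {
  double prenorm;
};

// One Heun (predictor-corrector) step from grid index i to i+1.
// chist holds gamma*<sigma_z> along the trajectory up to index i; the slot
// i+1 is written provisionally (predictor) then finalized by the caller.
StepResult heun_step(const DriftCtx& ctx, const cx_vec& alpha,
                     std::vector<double>& chist, const cx_vec& z,
                     const cx_vec& g0, const cx_vec& g1, double dt, int i,
                     cx_vec& psi, bool rk4) {
  cplx zt_i = z(i) + shift_conv(alpha, chist, i, dt);
  cx_vec k1 = drift_eval(ctx, psi, std::conj(zt_i), g0(i), g1(i));
  cx_vec psi_p = psi + dt * k1;
  double np = norm(psi_p);
  if (np < 1e-12) Rcpp::stop("Trajectory norm collapse at step %d.", i);
  psi_p /= np;
  chist[i + 1] = ctx.gamma *
      std::real(cdot(psi_p, ctx.Sz * psi_p));
  cplx zt_n = z(i + 1) + shift_conv(alpha, chist, i + 1, dt);

  cx_vec out;
  if (!rk4) {
    cx_vec k2 = drift_eval(ctx, psi_p, std::conj(zt_n), g0(i + 1), g1(i + 1));
    out = psi + 0.5 * dt * (k1 + k2);
  } else {
    cplx zt_m = 0.5 * (zt_i + zt_n);
    cplx g0m = 0.5 * (g0(i) + g0(i + 1));
    cplx g1m = 0.5 * (g1(i) + g1(i + 1));
    cx_vec s2 = psi + 0.5 * dt * k1;  s2 /= norm(s2);
    cx_vec k2 = drift_eval(ctx, s2, std::conj(zt_m), g0m, g1m);
    cx_vec s3 = psi + 0.5 * dt * k2;  s3 /= norm(s3);
    cx_vec k3 = drift_eval(ctx, s3, std::conj(zt_m), g0m, g1m);
    cx_vec s4 = psi + dt * k3;        s4 /= norm(s4);
    cx_vec k4 = drift_eval(ctx, s4, std::conj(zt_n), g0(i + 1), g1(i + 1));
    out = psi + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  StepResult r;
  r.prenorm = norm(out);
  if (r.prenorm < 1e-12) Rcpp::stop("Trajectory norm collapse at step %d.", i);
  psi = out / r.prenorm;
  return r;
}

} // namespace

// Propagate a single trajectory; returns the normalized state series and
// the pre-normalization norms.
// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_propagate(const arma::cx_mat& H, const arma::cx_mat& Sz,
                         const arma::cx_mat& Sy, double gamma, double delta,
                         const arma::cx_vec& alpha, const arma::cx_vec& g0,
                         const arma::cx_vec& g1, const arma::cx_vec& z,
                         const arma::cx_vec& psi0, double dt,
                         double bracket_factor, bool rk4,
                         const arma::vec& kick_times,
                         const arma::vec& kick_marks,
                         const arma::cx_mat& kickV, const arma::vec& kickE,
                         double kick_scale) {
  const int n = z.n_elem;
  cx_mat Szz = Sz * Sz, Szy = Sz * Sy;
  DriftCtx ctx{H, Sz, Sy, Szz, Szy, gamma, delta, bracket_factor};
  KickSet ks;
  ks.active = kick_times.n_elem > 0 && kickE.n_elem > 0;
  if (ks.active) { ks.V = kickV; ks.E = kickE; ks.scale = kick_scale; ks.nf = kickE.n_elem; }

  cx_vec psi = psi0 / norm(psi0);
  cx_mat out(psi.n_elem, n);
  vec norms(n, fill::ones);
  std::vector<double> chist(n, 0.0);
  chist[0] = gamma * std::real(cdot(psi, Sz * psi));
  out.col(0) = psi;
  unsigned int kidx = 0;
  for (int i = 0; i < n - 1; ++i) {
    StepResult r = heun_step(ctx, alpha, chist, z, g0, g1, dt, i, psi, rk4);
    double t_next = (i + 1) * dt;
    while (ks.active && kidx < kick_times.n_elem &&
           kick_times(kidx) <= t_next + 1e-12) {
      ks.apply(psi, kick_marks(kidx));
      ++kidx;
    }
    psi /= norm(psi);
    chist[i + 1] = gamma * std::real(cdot(psi, Sz * psi));
    norms(i + 1) = r.prenorm;
    out.col(i + 1) = psi;
  }
  return Rcpp::List::create(Rcpp::Named("psi") = out,
                            Rcpp::Named("norms") = norms);
}

// Ensemble driver: propagates n_traj trajectories (columns of `paths`) and
// accumulates the reduced density matrix and observables.
// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_ensemble(const arma::cx_mat& H, const arma::cx_mat& Sz,
                        const arma::cx_mat& Sy, double gamma, double delta,
                        const arma::cx_vec& alpha, const arma::cx_vec& g0,
                        const arma::cx_vec& g1, const arma::cx_mat& paths,
                        const arma::cx_vec& psi0, double dt,
                        double bracket_factor, bool rk4,
                        const Rcpp::List& kick_times,
                        const Rcpp::List& kick_marks,
                        const arma::cx_mat& kickV, const arma::vec& kickE,
                        double kick_scale, const arma::cx_mat& Nop) {
  const int n = paths.n_rows;
  const int ntraj = paths.n_cols;
  const int d = psi0.n_elem;
  const int half = d / 2;
  const bool have_kicks = kick_times.size() > 0 && kickE.n_elem > 0;
  const bool have_n = Nop.n_rows == (unsigned)d;

  cx_mat Szz = Sz * Sz, Szy = Sz * Sy;
  DriftCtx ctx{H, Sz, Sy, Szz, Szy, gamma, delta, bracket_factor};
  KickSet ks;
  ks.active = false;
  if (have_kicks) { ks.V = kickV; ks.E = kickE; ks.scale = kick_scale; ks.nf = kickE.n_elem; }

  cx_cube rho_sum(d, d, n, fill::zeros);
  vec pa_sum(n, fill::zeros), pa_sq(n, fill::zeros), nvib_sum(n, fill::zeros);

  std::vector<double> chist(n, 0.0);
  for (int tr = 0; tr < ntraj; ++tr) {
    cx_vec psi = psi0 / norm(psi0);
    cx_vec z = paths.col(tr);
    vec kt, km;
    if (have_kicks) {
      kt = Rcpp::as<vec>(kick_times[tr]);
      km = Rcpp::as<vec>(kick_marks[tr]);
      ks.active = kt.n_elem > 0;
    }
    std::fill(chist.begin(), chist.end(), 0.0);
    chist[0] = gamma * std::real(cdot(psi, Sz * psi));
    unsigned int kidx = 0;
    for (int i = 0; i < n; ++i) {
      if (i > 0) {
        heun_step(ctx, alpha, chist, z, g0, g1, dt, i - 1, psi, rk4);
        double t_next = i * dt;
        while (ks.active && kidx < kt.n_elem && kt(kidx) <= t_next + 1e-12) {
          ks.apply(psi, km(kidx));
          ++kidx;
        }
        psi /= norm(psi);
        chist[i] = gamma * std::real(cdot(psi, Sz * psi));
      }
      rho_sum.slice(i) += psi * psi.t();
      double pa = std::pow(norm(psi.subvec(half, d - 1)), 2);
      pa_sum(i) += pa;
      pa_sq(i) += pa * pa;
      if (have_n) nvib_sum(i) += std::real(cdot(psi, Nop * psi));
    }
    if (tr % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("rho_sum") = rho_sum,
                            Rcpp::Named("pa_sum") = pa_sum,
                            Rcpp::Named("pa_sq") = pa_sq,
                            Rcpp::Named("nvib_sum") = nvib_sum,
                            Rcpp::Named("n_traj") = ntraj);
}
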