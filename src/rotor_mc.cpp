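#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis kernel for the interfacial rotor layer.
//
// State: unit axes u[i] and head-height offsets dz[i] for the mobile
// (interfacial) molecules on a periodic 4-neighbor lattice.
// Energy (kT): E = -J sum_<ij> u_i.u_j - h sum_i u_iz + 0.5 kz sum_i dz_i^2.
// Proposals per molecule: symmetric axis rotation (fixed-kernel angle about
// a random perpendicular direction), axis inversion, or a Gaussian dz step.
// Equator-crossing axis proposals pay an extra barrier fb, applied
// symmetrically in both directions so the stationary distribution is the
// Boltzmann one; fb only slows hemisphere exchange.
//
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export]]
List rotor_mc_kernel(NumericMatrix u0, IntegerMatrix nbr, double J, double h,
                     double fb, double kz, double ang_step, double z_step,
                     int sweeps, int burn_in, int stride) {
  const int n = u0.nrow();
  std::vector<double> ux(n), uy(n), uz(n), dz(n, 0.0);
  for (int i = 0; i < n; ++i) {
    ux[i] = u0(i, 0); uy[i] = u0(i, 1); uz[i] = u0(i, 2);
  }
  const int n_frames = (sweeps - burn_in) / stride;
  NumericVector axis_out(n_frames * (R_xlen_t)n * 3);
  NumericMatrix dz_out(n_frames, n);

  // proposal log: subsample so the log stays small on long runs
  const R_xlen_t total = (R_xlen_t)sweeps * n;
  const R_xlen_t max_log = 20000;
  const R_xlen_t log_every = total / max_log > 0 ? total / max_log : 1;
  std::vector<double> log_rows;  // move, dE, p, u, accepted, crossed
  log_rows.reserve(6 * (max_log + 8));

  double att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  R_xlen_t counter = 0;
  int frame = 0;

  for (int s = 1; s <= sweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      ++counter;
      double sel = unif_rand();
      int move; // 0 axis rotation, 1 inversion, 2 z step
      if (sel < 0.45) move = 0; else if (sel < 0.55) move = 1; else move = 2;
      double de = 0.0, nux = 0, nuy = 0, nuz = 0, ndz = 0;
      bool crossed = false;
      if (move == 2) {
        ndz = dz[i] + norm_rand() * z_step;
        de = 0.5 * kz * (ndz * ndz - dz[i] * dz[i]);
      } else {
        if (move == 1) {
          nux = -ux[i]; nuy = -uy[i]; nuz = -uz[i];
        } else {
          // random direction perpendicular to u, rotate by |N(0, ang_step)|
          double tx, ty, tz, dot, nrm;
          do {
            tx = norm_rand(); ty = norm_rand(); tz = norm_rand();
            dot = tx * ux[i] + ty * uy[i] + tz * uz[i];
            tx -= dot * ux[i]; ty -= dot * uy[i]; tz -= dot * uz[i];
            nrm = std::sqrt(tx * tx + ty * ty + tz * tz);
          } while (nrm < 1e-12);
          tx /= nrm; ty /= nrm; tz /= nrm;
          double a = std::fabs(norm_rand()) * ang_step;
          double ca = std::cos(a), sa = std::sin(a);
          nux = ca * ux[i] + sa * tx;
          nuy = ca * uy[i] + sa * ty;
          nuz = ca * uz[i] + sa * tz;
          nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          nux /= nrm; nuy /= nrm; nuz /= nrm;
        }
        double sx = 0, sy = 0, sz = 0;
        for (int k = 0; k < 4; ++k) {
          int j = nbr(i, k);
          sx += ux[j]; sy += uy[j]; sz += uz[j];
        }
        de = -J * ((nux - ux[i]) * sx + (nuy - uy[i]) * sy +
                   (nuz - uz[i]) * sz) - h * (nuz - uz[i]);
        crossed = (nuz >= 0) != (uz[i] >= 0);
        if (crossed) de += fb;
      }
      double p = de <= 0 ? 1.0 : std::exp(-de);
      double u = unif_rand();
      bool accepted = u < p;
      att[move] += 1;
      if (accepted) {
        acc[move] += 1;
        if (move == 2) dz[i] = ndz;
        else { ux[i] = nux; uy[i] = nuy; uz[i] = nuz; }
      }
      if (counter % log_every == 0) {
        log_rows.push_back(move);
        log_rows.push_back(de);
        log_rows.push_back(p);
        log_rows.push_back(u);
        log_rows.push_back(accepted ? 1.0 : 0.0);
        log_rows.push_back(crossed ? 1.0 : 0.0);
      }
    }
    if (s > burn_in && (s - burn_in) % stride == 0 && frame < n_frames) {
      for (int i = 0; i < n; ++i) {
        axis_out[frame + n_frames * (R_xlen_t)i] = ux[i];
        axis_out[frame + n_frames * ((R_xlen_t)n + i)] = uy[i];
        axis_out[frame + n_frames * (2 * (R_xlen_t)n + i)] = uz[i];
        dz_out(frame, i) = dz[i];
      }
      ++frame;
    }
  }

  NumericMatrix logm(log_rows.size() / 6, 6);
  for (R_xlen_t r = 0; r < logm.nrow(); ++r)
    for (int c = 0; c < 6; ++c) logm(r, c) = log_rows[6 * r + c];

  axis_out.attr("dim") = IntegerVector::create(n_frames, n, 3);
  NumericMatrix accm(3, 2);
  for (int k = 0; k < 3; ++k) { accm(k, 0) = att[k]; accm(k, 1) = acc[k]; }
  colnames(accm) = CharacterVector::create("attempted", "accepted");
  rownames(accm) = CharacterVector::create("rotation", "inversion", "z");
  return List::create(_["axis"] = axis_out, _["dz"] = dz_out,
                      _["log"] = logm, _["acceptance"] = accm);
}
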