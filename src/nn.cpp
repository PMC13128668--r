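// Training backend for the half-life classifier network:
//   input image (d_local x L_padded)
//     -> [conv KxK, F filters -> ReLU -> 2x2 average pool -> dropout] x 2
//     -> flatten -> concat with processed feature vector
//     -> n_layers dense (ReLU, dropout) -> dense(1) -> sigmoid
// Binary cross-entropy, Adam updates. Convolutions run as im2col + GEMM.
// All randomness (dropout, and the caller's shuffling / initialisation)
// flows through R's RNG, so a single set.seed() makes training bit
// reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims {
  int H, W, K, F;
  int h1, w1, h2, w2, h3, w3, h4, w4, q, m, nlayers, input_dim;
  std::vector<int> units;
};

Dims read_dims(const List& d) {
  Dims s;
  s.H = d["H"]; s.W = d["W"]; s.K = d["K"]; s.F = d["F"];
  s.h1 = d["h1"]; s.w1 = d["w1"]; s.h2 = d["h2"]; s.w2 = d["w2"];
  s.h3 = d["h3"]; s.w3 = d["w3"]; s.h4 = d["h4"]; s.w4 = d["w4"];
  s.q = d["q"]; s.m = d["m"]; s.nlayers = d["nlayers"];
  s.input_dim = d["input_dim"];
  IntegerVector u = d["units"];
  s.units.assign(u.begin(), u.end());
  return s;
}

inline arma::mat mview(NumericMatrix& x) {
  return arma::mat(x.begin(), x.nrow(), x.ncol(), false, true);
}
inline arma::vec vview(NumericVector& x) {
  return arma::vec(x.begin(), x.size(), false, true);
}

void im2col1(const arma::mat& X, arma::mat& C, const Dims& d) {
  for (int j1 = 0; j1 < d.w1; ++j1)
    for (int i1 = 0; i1 < d.h1; ++i1) {
      const int c = i1 + j1 * d.h1;
      for (int kj = 0; kj < d.K; ++kj)
        for (int ki = 0; ki < d.K; ++ki)
          C(ki + kj * d.K, c) = X(i1 + ki, j1 + kj);
    }
}

// channels of P (F x h2*w2) laid out as h2 x w2 images
void im2col2(const arma::mat& P, arma::mat& C, const Dims& d) {
  for (int j3 = 0; j3 < d.w3; ++j3)
    for (int i3 = 0; i3 < d.h3; ++i3) {
      const int c = i3 + j3 * d.h3;
      for (int f = 0; f < d.F; ++f)
        for (int kj = 0; kj < d.K; ++kj)
          for (int ki = 0; ki < d.K; ++ki)
            C(f * d.K * d.K + ki + kj * d.K, c) =
              P(f, (i3 + ki) + (j3 + kj) * d.h2);
    }
}

void col2im2(const arma::mat& dC, arma::mat& dP, const Dims& d) {
  dP.zeros();
  for (int j3 = 0; j3 < d.w3; ++j3)
    for (int i3 = 0; i3 < d.h3; ++i3) {
      const int c = i3 + j3 * d.h3;
      for (int f = 0; f < d.F; ++f)
        for (int kj = 0; kj < d.K; ++kj)
          for (int ki = 0; ki < d.K; ++ki)
            dP(f, (i3 + ki) + (j3 + kj) * d.h2) +=
              dC(f * d.K * d.K + ki + kj * d.K, c);
    }
}

void avgpool(const arma::mat& A, arma::mat& P, int hin, int hout, int wout) {
  for (int f = 0; f < (int)A.n_rows; ++f)
    for (int j = 0; j < wout; ++j)
      for (int i = 0; i < hout; ++i)
        P(f, i + j * hout) = 0.25 *
          (A(f, 2 * i + 2 * j * hin) + A(f, 2 * i + 1 + 2 * j * hin) +
           A(f, 2 * i + (2 * j + 1) * hin) + A(f, 2 * i + 1 + (2 * j + 1) * hin));
}

void unpool(const arma::mat& dP, arma::mat& dA, int hin, int hout, int wout) {
  dA.zeros();
  for (int f = 0; f < (int)dP.n_rows; ++f)
    for (int j = 0; j < wout; ++j)
      for (int i = 0; i < hout; ++i) {
        const double g = 0.25 * dP(f, i + j * hout);
        dA(f, 2 * i + 2 * j * hin) += g;
        dA(f, 2 * i + 1 + 2 * j * hin) += g;
        dA(f, 2 * i + (2 * j + 1) * hin) += g;
        dA(f, 2 * i + 1 + (2 * j + 1) * hin) += g;
      }
}

void dropout_mask(arma::mat& M, double p) {
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword i = 0; i < M.n_elem; ++i)
    M(i) = (R::unif_rand() < p) ? 0.0 : scale;
}
void dropout_mask(arma::vec& M, double p) {
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword i = 0; i < M.n_elem; ++i)
    M(i) = (R::unif_rand() < p) ? 0.0 : scale;
}

struct Workspace {
  arma::mat C1, A1, P1, M1, P1d, C2, A2, P2, M2, P2d;
  arma::mat dA1, dP1, dA2, dP2, dC2;
  std::vector<arma::vec> act, actd, mask;
  arma::vec x0;
  Workspace(const Dims& d) {
    C1.set_size(d.K * d.K, d.h1 * d.w1);
    A1.set_size(d.F, d.h1 * d.w1);
    P1.set_size(d.F, d.h2 * d.w2);
    M1.set_size(d.F, d.h2 * d.w2);
    P1d.set_size(d.F, d.h2 * d.w2);
    C2.set_size(d.F * d.K * d.K, d.h3 * d.w3);
    A2.set_size(d.F, d.h3 * d.w3);
    P2.set_size(d.F, d.h4 * d.w4);
    M2.set_size(d.F, d.h4 * d.w4);
    P2d.set_size(d.F, d.h4 * d.w4);
    dA1.set_size(d.F, d.h1 * d.w1);
    dP1.set_size(d.F, d.h2 * d.w2);
    dA2.set_size(d.F, d.h3 * d.w3);
    dP2.set_size(d.F, d.h4 * d.w4);
    dC2.set_size(d.F * d.K * d.K, d.h3 * d.w3);
    x0.set_size(d.input_dim);
    act.resize(d.nlayers);
    actd.resize(d.nlayers);
    mask.resize(d.nlayers);
    for (int l = 0; l < d.nlayers; ++l) {
      act[l].set_size(d.units[l]);
      actd[l].set_size(d.units[l]);
      mask[l].set_size(d.units[l]);
    }
  }
};

// forward pass for one sample; returns the sigmoid probability
double forward_sample(const arma::mat& X, const arma::rowvec& feat,
                      const arma::mat& W1, const arma::vec& b1,
                      const arma::mat& W2, const arma::vec& b2,
                      List& Wd, List& bd,
                      const arma::mat& Wout, const arma::vec& bout,
                      const Dims& d, Workspace& ws,
                      bool train, double pdrop) {
  im2col1(X, ws.C1, d);
  ws.A1 = W1 * ws.C1;
  ws.A1.each_col() += b1;
  ws.A1.transform([](double v) { return v > 0 ? v : 0.0; });
  avgpool(ws.A1, ws.P1, d.h1, d.h2, d.w2);
  if (train && pdrop > 0) {
    dropout_mask(ws.M1, pdrop);
    ws.P1d = ws.P1 % ws.M1;
  } else {
    ws.P1d = ws.P1;
  }
  im2col2(ws.P1d, ws.C2, d);
  ws.A2 = W2 * ws.C2;
  ws.A2.each_col() += b2;
  ws.A2.transform([](double v) { return v > 0 ? v : 0.0; });
  avgpool(ws.A2, ws.P2, d.h3, d.h4, d.w4);
  if (train && pdrop > 0) {
    dropout_mask(ws.M2, pdrop);
    ws.P2d = ws.P2 % ws.M2;
  } else {
    ws.P2d = ws.P2;
  }
  ws.x0.head(d.q) = arma::vectorise(ws.P2d);
  ws.x0.tail(d.m) = feat.t();
  const arma::vec* prev = &ws.x0;
  for (int l = 0; l < d.nlayers; ++l) {
    NumericMatrix Wl_ = as<NumericMatrix>(Wd[l]);
    NumericVector bl_ = as<NumericVector>(bd[l]);
    arma::mat Wl(Wl_.begin(), Wl_.nrow(), Wl_.ncol(), false, true);
    arma::vec bl(bl_.begin(), bl_.size(), false, true);
    ws.act[l] = Wl * (*prev) + bl;
    ws.act[l].transform([](double v) { return v > 0 ? v : 0.0; });
    if (train && pdrop > 0) {
      dropout_mask(ws.mask[l], pdrop);
      ws.actd[l] = ws.act[l] % ws.mask[l];
    } else {
      ws.actd[l] = ws.act[l];
    }
    prev = &ws.actd[l];
  }
  const double logit = arma::dot(Wout.row(0).t(), *prev) + bout(0);
  return 1.0 / (1.0 + std::exp(-logit));
}

void adam_update(arma::mat& th, arma::mat& g, arma::mat& m, arma::mat& v,
                 double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  th -= lr * (m / (1 - std::pow(b1, t))) /
        (arma::sqrt(v / (1 - std::pow(b2, t))) + eps);
}
void adam_update(arma::vec& th, arma::vec& g, arma::vec& m, arma::vec& v,
                 double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  th -= lr * (m / (1 - std::pow(b1, t))) /
        (arma::sqrt(v / (1 - std::pow(b2, t))) + eps);
}

}  // namespace

// One epoch of minibatch Adam over the samples in `order` (0-based).
// Updates params / mstate / vstate in place; returns the mean training
// loss and the advanced Adam step counter.
// [[Rcpp::export]]
List nn_epoch_cpp(List params, List mstate, List vstate, double step,
                  const arma::cube& ximg, const arma::mat& xfeat,
                  const arma::vec& y, const IntegerVector& order,
                  const List& dims, double lr, double pdrop,
                  int batch_size) {
  Dims d = read_dims(dims);
  NumericMatrix W1_ = params["W1"], W2_ = params["W2"], Wout_ = params["Wout"];
  NumericVector b1_ = params["b1"], b2_ = params["b2"], bout_ = params["bout"];
  arma::mat W1 = mview(W1_), W2 = mview(W2_), Wout = mview(Wout_);
  arma::vec b1 = vview(b1_), b2 = vview(b2_), bout = vview(bout_);
  List Wd = params["Wd"], bd = params["bd"];
  List mWd = mstate["Wd"], mbd = mstate["bd"];
  List vWd = vstate["Wd"], vbd = vstate["bd"];
  NumericMatrix mW1_ = mstate["W1"], mW2_ = mstate["W2"], mWout_ = mstate["Wout"];
  NumericVector mb1_ = mstate["b1"], mb2_ = mstate["b2"], mbout_ = mstate["bout"];
  NumericMatrix vW1_ = vstate["W1"], vW2_ = vstate["W2"], vWout_ = vstate["Wout"];
  NumericVector vb1_ = vstate["b1"], vb2_ = vstate["b2"], vbout_ = vstate["bout"];
  arma::mat mW1 = mview(mW1_), mW2 = mview(mW2_), mWout = mview(mWout_);
  arma::vec mb1 = vview(mb1_), mb2 = vview(mb2_), mbout = vview(mbout_);
  arma::mat vW1 = mview(vW1_), vW2 = mview(vW2_), vWout = mview(vWout_);
  arma::vec vb1 = vview(vb1_), vb2 = vview(vb2_), vbout = vview(vbout_);

  Workspace ws(d);
  arma::mat gW1(arma::size(W1)), gW2(arma::size(W2)), gWout(arma::size(Wout));
  arma::vec gb1(arma::size(b1)), gb2(arma::size(b2)), gbout(arma::size(bout));
  std::vector<arma::mat> gWd(d.nlayers);
  std::vector<arma::vec> gbd(d.nlayers);
  for (int l = 0; l < d.nlayers; ++l) {
    NumericMatrix Wl_ = as<NumericMatrix>(Wd[l]);
    gWd[l].set_size(Wl_.nrow(), Wl_.ncol());
    gbd[l].set_size(Wl_.nrow());
  }

  const int n = order.size();
  double total_loss = 0.0;
  int n_batches = 0;
  for (int start = 0; start < n; start += batch_size) {
    const int end = std::min(start + batch_size, n);
    const int B = end - start;
    gW1.zeros(); gb1.zeros(); gW2.zeros(); gb2.zeros();
    gWout.zeros(); gbout.zeros();
    for (int l = 0; l < d.nlayers; ++l) { gWd[l].zeros(); gbd[l].zeros(); }
    double batch_loss = 0.0;
    for (int s = start; s < end; ++s) {
      const int i = order[s];
      const arma::mat& X = ximg.slice(i);
      const arma::rowvec feat = d.m > 0 ? xfeat.row(i) : arma::rowvec();
      const double p = forward_sample(X, feat, W1, b1, W2, b2, Wd, bd,
                                      Wout, bout, d, ws, true, pdrop);
      const double yi = y(i);
      const double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
      batch_loss += -(yi * std::log(pc) + (1 - yi) * std::log(1 - pc));
      if (!std::isfinite(batch_loss)) stop("non-finite training loss");

      // backward
      const double dlogit = (p - yi) / B;
      const arma::vec& alast = d.nlayers > 0 ? ws.actd[d.nlayers - 1] : ws.x0;
      gWout += dlogit * alast.t();
      gbout(0) += dlogit;
      arma::vec da = Wout.row(0).t() * dlogit;
      for (int l = d.nlayers - 1; l >= 0; --l) {
        if (pdrop > 0) da %= ws.mask[l];
        arma::vec dpre = da % arma::conv_to<arma::vec>::from(ws.act[l] > 0);
        const arma::vec& aprev = l > 0 ? ws.actd[l - 1] : ws.x0;
        gWd[l] += dpre * aprev.t();
        gbd[l] += dpre;
        NumericMatrix Wl_ = as<NumericMatrix>(Wd[l]);
        arma::mat Wl(Wl_.begin(), Wl_.nrow(), Wl_.ncol(), false, true);
        da = Wl.t() * dpre;
      }
      ws.dP2 = arma::reshape(da.head(d.q), d.F, d.h4 * d.w4);
      if (pdrop > 0) ws.dP2 %= ws.M2;
      unpool(ws.dP2, ws.dA2, d.h3, d.h4, d.w4);
      ws.dA2 %= arma::conv_to<arma::mat>::from(ws.A2 > 0);
      gW2 += ws.dA2 * ws.C2.t();
      gb2 += arma::sum(ws.dA2, 1);
      ws.dC2 = W2.t() * ws.dA2;
      col2im2(ws.dC2, ws.dP1, d);
      if (pdrop > 0) ws.dP1 %= ws.M1;
      unpool(ws.dP1, ws.dA1, d.h1, d.h2, d.w2);
      ws.dA1 %= arma::conv_to<arma::mat>::from(ws.A1 > 0);
      gW1 += ws.dA1 * ws.C1.t();
      gb1 += arma::sum(ws.dA1, 1);
    }
    total_loss += batch_loss;
    ++n_batches;
    step += 1.0;
    adam_update(W1, gW1, mW1, vW1, lr, step);
    adam_update(b1, gb1, mb1, vb1, lr, step);
    adam_update(W2, gW2, mW2, vW2, lr, step);
    adam_update(b2, gb2, mb2, vb2, lr, step);
    for (int l = 0; l < d.nlayers; ++l) {
      NumericMatrix Wl_ = as<NumericMatrix>(Wd[l]);
      NumericVector bl_ = as<NumericVector>(bd[l]);
      NumericMatrix mWl_ = as<NumericMatrix>(mWd[l]);
      NumericVector mbl_ = as<NumericVector>(mbd[l]);
      NumericMatrix vWl_ = as<NumericMatrix>(vWd[l]);
      NumericVector vbl_ = as<NumericVector>(vbd[l]);
      arma::mat Wl = mview(Wl_), mWl = mview(mWl_), vWl = mview(vWl_);
      arma::vec bl = vview(bl_), mbl = vview(mbl_), vbl = vview(vbl_);
      adam_update(Wl, gWd[l], mWl, vWl, lr, step);
      adam_update(bl, gbd[l], mbl, vbl, lr, step);
    }
    adam_update(Wout, gWout, mWout, vWout, lr, step);
    adam_update(bout, gbout, mbout, vbout, lr, step);
  }
  (void)n_batches;
  return List::create(_["train_loss"] = total_loss / n,
                      _["step"] = step);
}

// Forward pass (no dropout) over all samples; returns probabilities of the
// positive (long-lived) class.
// [[Rcpp::export]]
NumericVector nn_forward_cpp(List params, const arma::cube& ximg,
                             const arma::mat& xfeat, const List& dims) {
  Dims d = read_dims(dims);
  NumericMatrix W1_ = params["W1"], W2_ = params["W2"], Wout_ = params["Wout"];
  NumericVector b1_ = params["b1"], b2_ = params["b2"], bout_ = params["bout"];
  arma::mat W1 = mview(W1_), W2 = mview(W2_), Wout = mview(Wout_);
  arma::vec b1 = vview(b1_), b2 = vview(b2_), bout = vview(bout_);
  List Wd = params["Wd"], bd = params["bd"];
  Workspace ws(d);
  const int n = ximg.n_slices;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const arma::rowvec feat = d.m > 0 ? xfeat.row(i) : arma::rowvec();
    out[i] = forward_sample(ximg.slice(i), feat, W1, b1, W2, b2, Wd, bd,
                            Wout, bout, d, ws, false, 0.0);
  }
  return out;
}
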