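// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson).
//
// Inputs are expected pre-conditioned by the R wrapper: centered, scaled to
// unit extent, tie-broken by a tiny deterministic jitter, and supplied in a
// randomized insertion order. Under those conditions plain double-precision
// circumsphere tests are reliable; exact predicates are not attempted.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
    int v[4];     // vertex indices
    int nb[4];    // nb[i] = tet sharing the face opposite v[i], -1 if none
    bool alive;
    double cc[3]; // circumcenter
    double r2;    // squared circumradius
};

inline double orient3d(const double *a, const double *b, const double *c,
                       const double *d) {
    const double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
    const double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
    const double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
    return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
           adz * (bdx * cdy - bdy * cdx);
}

// Circumcenter via the linear system 2 (b - a) . x = |b|^2 - |a|^2 (etc.).
// Returns false for (near-)degenerate tetrahedra; caller marks those with an
// effectively infinite circumsphere so they are destroyed eagerly.
bool circumsphere(const double *a, const double *b, const double *c,
                  const double *d, double *cc, double &r2) {
    double m[3][3], rhs[3];
    const double *pts[3] = {b, c, d};
    for (int i = 0; i < 3; ++i) {
        rhs[i] = 0.0;
        for (int j = 0; j < 3; ++j) {
            m[i][j] = pts[i][j] - a[j];
            rhs[i] += 0.5 * (pts[i][j] * pts[i][j] - a[j] * a[j]);
        }
    }
    const double det =
        m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
        m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
        m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
    if (std::fabs(det) < 1e-30) return false;
    const double inv = 1.0 / det;
    cc[0] = inv * (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                   m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                   m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2]));
    cc[1] = inv * (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                   rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                   m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]));
    cc[2] = inv * (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                   m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                   rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]));
    const double dx = cc[0] - a[0], dy = cc[1] - a[1], dz = cc[2] - a[2];
    r2 = dx * dx + dy * dy + dz * dz;
    return true;
}

struct FaceKey {
    int a, b, c; // sorted ascending
    bool operator==(const FaceKey &o) const {
        return a == o.a && b == o.b && c == o.c;
    }
};
struct FaceHash {
    std::size_t operator()(const FaceKey &f) const {
        std::uint64_t h = (std::uint64_t)f.a;
        h = h * 1000003u + (std::uint64_t)f.b;
        h = h * 1000003u + (std::uint64_t)f.c;
        return (std::size_t)(h ^ (h >> 32));
    }
};

inline FaceKey make_face(int a, int b, int c) {
    if (a > b) std::swap(a, b);
    if (b > c) std::swap(b, c);
    if (a > b) std::swap(a, b);
    FaceKey f = {a, b, c};
    return f;
}

class Triangulation {
public:
    std::vector<double> pts; // flat xyz, n + 4 super vertices
    std::vector<Tet> tets;
    int n; // real points

    const double *P(int i) const { return &pts[3 * i]; }

    void computeSphere(Tet &t) {
        if (!circumsphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]),
                          t.cc, t.r2)) {
            t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
            t.r2 = std::numeric_limits<double>::infinity();
        }
    }

    int addTet(int a, int b, int c, int d) {
        Tet t;
        if (orient3d(P(a), P(b), P(c), P(d)) < 0.0) std::swap(c, d);
        t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
        t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
        t.alive = true;
        computeSphere(t);
        tets.push_back(t);
        return (int)tets.size() - 1;
    }

    bool inSphere(const Tet &t, const double *p) const {
        if (!std::isfinite(t.r2)) return true;
        const double dx = p[0] - t.cc[0], dy = p[1] - t.cc[1],
                     dz = p[2] - t.cc[2];
        return dx * dx + dy * dy + dz * dz < t.r2 * (1.0 + 1e-12);
    }

    // true if p inside (or on boundary of) tet
    bool contains(int ti, const double *p) const {
        const Tet &t = tets[ti];
        for (int i = 0; i < 4; ++i) {
            const double *q[4] = {P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3])};
            q[i] = p;
            if (orient3d(q[0], q[1], q[2], q[3]) < -1e-14) return false;
        }
        return true;
    }

    // Visibility walk from `start`; -1 if the walk fails (caller falls back
    // to a linear scan).
    int locate(int start, const double *p) const {
        int cur = start;
        const int maxSteps = (int)tets.size() + 64;
        for (int step = 0; step < maxSteps; ++step) {
            if (cur < 0 || !tets[cur].alive) return -1;
            const Tet &t = tets[cur];
            int next = -1;
            for (int i = 0; i < 4; ++i) {
                const double *q[4] = {P(t.v[0]), P(t.v[1]), P(t.v[2]),
                                      P(t.v[3])};
                q[i] = p;
                if (orient3d(q[0], q[1], q[2], q[3]) < -1e-14) {
                    next = t.nb[i];
                    break;
                }
            }
            if (next == -1) return cur; // no separating face: inside
            cur = next;
        }
        return -1;
    }

    void insert(int pi, int &hint) {
        const double *p = P(pi);
        int t0 = locate(hint, p);
        if (t0 < 0 || !tets[t0].alive || !contains(t0, p)) {
            t0 = -1;
            for (int i = (int)tets.size() - 1; i >= 0; --i) {
                if (tets[i].alive && contains(i, p)) { t0 = i; break; }
            }
            if (t0 < 0) stop("point location failed (degenerate geometry?)");
        }

        // Cavity: BFS over tets whose circumsphere contains p.
        std::vector<int> cavity;
        std::vector<char> inCav(tets.size(), 0);
        std::vector<int> stack;
        stack.push_back(t0);
        inCav[t0] = 1;
        while (!stack.empty()) {
            int ti = stack.back();
            stack.pop_back();
            cavity.push_back(ti);
            for (int i = 0; i < 4; ++i) {
                int nbi = tets[ti].nb[i];
                if (nbi >= 0 && tets[nbi].alive && !inCav[nbi] &&
                    inSphere(tets[nbi], p)) {
                    inCav[nbi] = 1;
                    stack.push_back(nbi);
                }
            }
        }

        // Boundary faces of the cavity, with the surviving outside tet.
        struct BFace { int a, b, c, outside; };
        std::vector<BFace> bfaces;
        for (int ti : cavity) {
            const Tet &t = tets[ti];
            for (int i = 0; i < 4; ++i) {
                int nbi = t.nb[i];
                if (nbi < 0 || !inCav[nbi]) {
                    BFace f;
                    f.a = t.v[(i + 1) % 4];
                    f.b = t.v[(i + 2) % 4];
                    f.c = t.v[(i + 3) % 4];
                    f.outside = nbi;
                    bfaces.push_back(f);
                }
            }
        }
        for (int ti : cavity) tets[ti].alive = false;

        // Retriangulate: one new tet per boundary face.
        std::unordered_map<FaceKey, std::pair<int, int>, FaceHash> open;
        open.reserve(bfaces.size() * 3);
        int lastNew = -1;
        for (const BFace &f : bfaces) {
            int ni = addTet(pi, f.a, f.b, f.c);
            lastNew = ni;
            Tet &nt = tets[ni];
            // face opposite the new point is the boundary face itself
            int pSlot = -1;
            for (int i = 0; i < 4; ++i) if (nt.v[i] == pi) pSlot = i;
            nt.nb[pSlot] = f.outside;
            if (f.outside >= 0) {
                Tet &ot = tets[f.outside];
                FaceKey bk = make_face(f.a, f.b, f.c);
                for (int i = 0; i < 4; ++i) {
                    FaceKey ok = make_face(ot.v[(i + 1) % 4],
                                           ot.v[(i + 2) % 4],
                                           ot.v[(i + 3) % 4]);
                    if (ok == bk) { ot.nb[i] = ni; break; }
                }
            }
            // stitch the three faces through p to sibling new tets
            for (int i = 0; i < 4; ++i) {
                if (i == pSlot) continue;
                FaceKey k = make_face(nt.v[(i + 1) % 4], nt.v[(i + 2) % 4],
                                      nt.v[(i + 3) % 4]);
                auto it = open.find(k);
                if (it == open.end()) {
                    open[k] = std::make_pair(ni, i);
                } else {
                    int oi = it->second.first, os = it->second.second;
                    nt.nb[i] = oi;
                    tets[oi].nb[os] = ni;
                    open.erase(it);
                }
            }
        }
        if (!open.empty())
            stop("cavity retriangulation failed (non-star-shaped cavity)");
        hint = lastNew;
    }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix xyz, IntegerVector order) {
    const int n = xyz.nrow();
    if (n < 4) stop("need at least 4 points");

    Triangulation T;
    T.n = n;
    T.pts.resize(3 * (n + 4));
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j) T.pts[3 * i + j] = xyz(i, j);

    // Super-tetrahedron (regular, circumradius ~ L*sqrt(3)) enclosing the
    // unit-scaled data by a wide margin.
    const double L = 1e3;
    const double sv[4][3] = {
        {L, L, L}, {L, -L, -L}, {-L, L, -L}, {-L, -L, L}};
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 3; ++j) T.pts[3 * (n + i) + j] = sv[i][j];

    T.tets.reserve(8 * (std::size_t)n + 64);
    T.addTet(n, n + 1, n + 2, n + 3);

    int hint = 0;
    for (int k = 0; k < n; ++k) {
        T.insert(order[k] - 1, hint);
        if (k % 512 == 0) Rcpp::checkUserInterrupt();
    }

    int m = 0;
    for (const Tet &t : T.tets) {
        if (!t.alive) continue;
        if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
        ++m;
    }
    IntegerMatrix out(m, 4);
    int r = 0;
    for (const Tet &t : T.tets) {
        if (!t.alive) continue;
        if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
        for (int j = 0; j < 4; ++j) out(r, j) = t.v[j] + 1;
        ++r;
    }
    return out;
}
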