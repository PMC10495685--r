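"""Line-delimited JSON LP service around scipy.optimize.linprog (HiGHS).

Protocol: one JSON request per line on stdin, one JSON reply per line on
stdout. A request is {"problems": [p, ...]} or {"cmd": "quit"}. Each problem
p is a minimization with
  n      number of variables
  c      objective (length n)
  lb, ub variable bounds (+-1e30 and beyond mean unbounded)
  eq     optional {"m", "i", "j", "x", "rhs"} sparse triplet, 0-based, A x = rhs
  le     optional, same layout, A x <= rhs
Replies: {"ok": true, "results": [{"status", "message", "x", "obj"}, ...]}.
status follows scipy: 0 optimal, 1 iteration limit, 2 infeasible,
3 unbounded, 4 numerical trouble.
"""
import sys
import json

import numpy as np
from scipy.sparse import csc_matrix
from scipy.optimize import linprog

BIG = 1e29


def _mat(spec, n):
    i = np.asarray(spec["i"], dtype=int)
    j = np.asarray(spec["j"], dtype=int)
    x = np.asarray(spec["x"], dtype=float)
    return csc_matrix((x, (i, j)), shape=(int(spec["m"]), n)), np.asarray(
        spec["rhs"], dtype=float
    )


def solve_one(p):
    n = int(p["n"])
    c = np.asarray(p["c"], dtype=float)
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    bounds = [
        (None if l < -BIG else l, None if u > BIG else u) for l, u in zip(lb, ub)
    ]
    A_eq = b_eq = A_ub = b_ub = None
    if p.get("eq") and int(p["eq"]["m"]) > 0:
        A_eq, b_eq = _mat(p["eq"], n)
    if p.get("le") and int(p["le"]["m"]) > 0:
        A_ub, b_ub = _mat(p["le"], n)
    res = linprog(
        c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq, bounds=bounds,
        method="highs",
    )
    out = {"status": int(res.status), "message": str(res.message)}
    if res.status == 0:
        out["x"] = [float(v) for v in res.x]
        out["obj"] = float(res.fun)
    return out


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
        except Exception as ex:  # malformed request: report, keep serving
            sys.stdout.write(json.dumps({"ok": False, "error": str(ex)}) + "\n")
            sys.stdout.flush()
            continue
        if req.get("cmd") == "quit":
            break
        try:
            results = [solve_one(p) for p in req["problems"]]
            sys.stdout.write(json.dumps({"ok": True, "results": results}) + "\n")
        except Exception as ex:
            sys.stdout.write(json.dumps({"ok": False, "error": str(ex)}) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
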