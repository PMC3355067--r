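"""LP/MILP solving helper backed by scipy's HiGHS interface.

Two modes:
  milp_server.py IN.json OUT.json      solve one batch and exit
  milp_server.py --serve REQ RESP      create two FIFOs and answer
                                       line-delimited JSON batches until EOF

Batch payload: {"tasks": [task, ...]}; response: {"results": [result, ...]}.
A task is either {"type": "ping"} or a MILP:
  {"id": any, "sense": "max"|"min", "n": int, "m": int,
   "c": [...], "A": {"i": [...], "j": [...], "x": [...]},  # 1-based triplets
   "rlb": [...], "rub": [...], "lb": [...], "ub": [...],
   "vtype": [0|1, ...],            # 1 = integer variable
   "mip_gap": float, "time_limit": float}
Magnitudes >= 1e29 encode +/-infinity (JSON has no Inf literal).
"""

import json
import os
import sys

# scipy/numpy are imported lazily so that --serve mode creates its FIFOs
# immediately; the client waits on their existence.
np = None
sparse = None
_milp = None

BIG = 1e29
STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "error"}


def _ensure_solver():
    global np, sparse, _milp
    if np is None:
        import numpy
        from scipy import sparse as sp
        from scipy import optimize
        np = numpy
        sparse = sp
        _milp = optimize
    return _milp


def _vec(v, n, dtype=float):
    a = np.atleast_1d(np.asarray(v, dtype=dtype))
    if a.size == 1 and n > 1:
        a = np.repeat(a, n)
    return a


def _inf(a):
    a = np.array(a, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_task(task):
    _ensure_solver()
    if task.get("type") == "ping":
        import scipy
        return {"id": task.get("id"), "status": "ok",
                "scipy": scipy.__version__}
    try:
        n = int(task["n"])
        m = int(task["m"])
        sense = task.get("sense", "min")
        c = _vec(task["c"], n)
        obj = -c if sense == "max" else c
        integrality = _vec(task.get("vtype", 0), n, dtype=int)
        bounds = _milp.Bounds(_inf(_vec(task["lb"], n)),
                              _inf(_vec(task["ub"], n)))
        constraints = []
        if m > 0:
            ai = _vec(task["A"]["i"], 0, dtype=int) - 1
            aj = _vec(task["A"]["j"], 0, dtype=int) - 1
            ax = _vec(task["A"]["x"], 0)
            A = sparse.csc_matrix((ax, (ai, aj)), shape=(m, n))
            constraints = _milp.LinearConstraint(
                A, _inf(_vec(task["rlb"], m)), _inf(_vec(task["rub"], m)))
        options = {"time_limit": float(task.get("time_limit", 300.0))}
        if task.get("mip_gap") is not None:
            options["mip_rel_gap"] = float(task["mip_gap"])
        res = _milp.milp(c=obj, constraints=constraints,
                         integrality=integrality, bounds=bounds,
                         options=options)
        out = {"id": task.get("id"),
               "status": STATUS.get(res.status, "error")}
        if res.x is not None:
            out["objective"] = float(-res.fun if sense == "max" else res.fun)
            out["x"] = [float(v) for v in res.x]
        return out
    except Exception as exc:  # report, never crash the batch
        return {"id": task.get("id"), "status": "error", "message": str(exc)}


def handle(payload):
    req = json.loads(payload)
    return json.dumps(
        {"results": [solve_task(t) for t in req.get("tasks", [])]})


def serve(req_path, resp_path):
    os.mkfifo(req_path)
    os.mkfifo(resp_path)
    with open(req_path, "r") as req:
        resp = None
        try:
            for line in req:
                line = line.strip()
                if not line:
                    continue
                if line == '{"cmd":"shutdown"}':
                    break
                answer = handle(line)
                if resp is None:
                    resp = open(resp_path, "w")
                resp.write(answer + "\n")
                resp.flush()
        finally:
            if resp is not None:
                resp.close()
            for p in (req_path, resp_path):
                try:
                    os.unlink(p)
                except OSError:
                    pass


def main(argv):
    if len(argv) >= 3 and argv[0] == "--serve":
        serve(argv[1], argv[2])
    else:
        with open(argv[0]) as fh:
            payload = fh.read()
        with open(argv[1], "w") as fh:
            fh.write(handle(payload))


if __name__ == "__main__":
    main(sys.argv[1:])
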