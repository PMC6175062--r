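# Population PK parameters for the rifampicin / coproporphyrin I /
# rosuvastatin models.  Layout mirrors the estimation report: fixed effects
# (typical values), interindividual (IIV) and interoccasion (IOV)
# variability as %CV of the exponential random-effect model, and combined
# proportional + additive residual error per observation stream.
#
# Units: rates 1/h or nM/h as annotated; clearances L/h; volumes L;
# Ki uM (total plasma concentration scale); rifampicin and rosuvastatin
# plasma concentrations uM; CPI plasma nM; CPI urine nmol; RSV urine umol.
version: "1.0"
constants:
  fu_rif: 0.11          # rifampicin unbound fraction in plasma
rifampicin:
  dose_mg: 600
  MW: 822.94
  fixed:
    ka: 2.09            # 1/h
    CL: 3.97            # L/h (apparent)
    V: 24.7             # L (apparent)
    MTT: 0.74           # h
    "n": 8.63           # transit compartments (continuous)
  iiv_cv: {ka: 46.0, CL: 30.7, V: 19.5, MTT: 69.1, "n": 24.3}
  iov_cv: {ka: 49.2, V: 6.6, MTT: 47.6}
  error:
    plasma: {prop: 0.313, add: 0.01}     # add in uM
cpi:
  fixed:
    ksyn: 12.7          # nM/h
    CLb: 12.3           # L/h
    CLR: 1.64           # L/h
    V: 6.59             # L
    V_rif: 3.4          # L, under rifampicin
    Ki: 1.15            # uM total
  iiv_cv: {ksyn: 2.9, CLb: 14.3, CLR: 9.5, V: 35.2, Ki: 18.8}
  iov_cv: {ksyn: 5.5, CLb: 18.3}
  error:
    plasma: {prop: 0.139, add: 0.001}    # add in nM
    urine: {prop: 0.342, add: 2.69}      # add in nmol
rosuvastatin:
  dose_mg: 5
  MW: 481.54
  fixed:
    ka: 0.287           # 1/h
    CLR: 8.48           # L/h
    CLb: 124.0          # L/h
    V1: 430.0           # L
    V1_rif: 2.98        # L, under rifampicin
    Q: 45.3             # L/h
    Q_rif: 5.03         # L/h, under rifampicin
    V2: 865.0           # L
    V2_rif: 128.0       # L, under rifampicin
    Ki: 2.23            # uM total
  iiv_cv: {ka: 15.4, CLR: 37.9, CLb: 34.4, V1: 21.8, Q: 45.2, Ki: 33.4}
  iov_cv: {ka: 17.7}
  error:
    plasma: {prop: 0.257, add: 0.00005}  # add = 0.05 nM expressed in uM
    urine: {prop: 0.578, add: 0.0001}    # add in umol
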