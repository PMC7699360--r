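# kind=titration
# f0=10000
# temperature=298
# ref_wavelength=322
# label=synthetic (seed 101)
concentration,intensity
5.0000000000000004e-06,9706.9039723178375
1.0000000000000001e-05,9486.0085267328832
1.5000000000000002e-05,9061.8087940142123
2.0000000000000002e-05,8835.7988991606398
2.5000000000000001e-05,8545.3228224545419
3.0000000000000001e-05,8328.0610752082212
3.5000000000000004e-05,8004.903132679995
4.0000000000000003e-05,7683.3071044829367
4.5000000000000003e-05,7508.5685103202932
5.0000000000000002e-05,7184.4405525907296
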