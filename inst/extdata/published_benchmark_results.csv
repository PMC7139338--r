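id,algorithm,avg,std
F1,GA,1.03e+03,5.79e+02
F1,PSO,1.83e+04,3.01e+03
F1,BBO,7.59e+01,2.75e+01
F1,FPA,2.01e+03,5.60e+02
F1,GWO,1.18e-27,1.47e-27
F1,BAT,6.59e+04,7.51e+03
F1,FA,7.11e-03,3.21e-03
F1,MFO,1.01e+03,3.05e+03
F1,DE,1.33e-03,5.92e-04
F2,GA,2.47e+01,5.68e+00
F2,PSO,3.58e+02,1.35e+03
F2,BBO,1.36e-03,7.45e-03
F2,FPA,3.22e+01,5.55e+00
F2,GWO,9.71e-17,5.60e-17
F2,BAT,2.71e+08,1.30e+09
F2,FA,4.34e-01,1.84e-01
F2,MFO,3.19e+01,2.06e+01
F2,DE,6.83e-03,2.06e-03
F3,GA,2.65e+04,3.44e+03
F3,PSO,4.05e+04,8.21e+03
F3,BBO,1.21e+04,2.69e+03
F3,FPA,1.41e+03,5.59e+02
F3,GWO,5.12e-05,2.03e-04
F3,BAT,1.38e+05,4.72e+04
F3,FA,1.66e+03,6.72e+02
F3,MFO,2.43e+04,1.41e+04
F3,DE,3.97e+04,5.37e+03
F4,GA,5.17e+01,1.05e+01
F4,PSO,4.39e+01,3.64e+00
F4,BBO,3.02e+01,4.39e+00
F4,FPA,2.38e+01,2.77e+00
F4,GWO,1.24e-06,1.94e-06
F4,BAT,8.51e+01,2.95e+00
F4,FA,1.11e-01,4.75e-02
F4,MFO,7.00e+01,7.06e+00
F4,DE,1.15e+01,2.37e+00
F5,GA,1.95e+04,1.31e+04
F5,PSO,1.96e+07,6.25e+06
F5,BBO,1.82e+03,9.40e+02
F5,FPA,3.17e+05,1.75e+05
F5,GWO,2.70e+01,7.78e-01
F5,BAT,2.10e+08,4.17e+07
F5,FA,7.97e+01,7.39e+01
F5,MFO,7.35e+03,2.26e+04
F5,DE,1.06e+02,1.01e+02
F6,GA,9.01e+02,2.84e+02
F6,PSO,1.87e+04,2.92e+03
F6,BBO,6.71e+01,2.20e+01
F6,FPA,1.70e+03,3.13e+02
F6,GWO,8.44e-01,3.18e-01
F6,BAT,6.69e+04,5.87e+03
F6,FA,6.94e-03,3.61e-03
F6,MFO,2.68e+03,5.84e+03
F6,DE,1.44e-03,5.38e-04
F7,GA,1.91e-01,1.50e-01
F7,PSO,1.07e+01,3.05e+00
F7,BBO,2.91e-03,1.83e-03
F7,FPA,3.41e-01,1.10e-01
F7,GWO,1.70e-03,1.06e-03
F7,BAT,4.57e+01,7.82e+00
F7,FA,6.62e-02,4.23e-02
F7,MFO,4.50e+00,9.21e+00
F7,DE,5.24e-02,1.37e-02
F8,GA,-1.26e+04,4.51e+00
F8,PSO,-3.86e+03,2.49e+02
F8,BBO,-1.24e+04,3.50e+01
F8,FPA,-6.45e+03,3.03e+02
F8,GWO,-5.97e+03,7.10e+02
F8,BAT,-2.33e+03,2.96e+02
F8,FA,-5.85e+03,1.16e+03
F8,MFO,-8.48e+03,7.98e+02
F8,DE,-6.82e+03,3.94e+02
F9,GA,9.04e+00,4.58e+00
F9,PSO,2.87e+02,1.95e+01
F9,BBO,0.00e+00,0.00e+00
F9,FPA,1.82e+02,1.24e+01
F9,GWO,2.19e+00,3.69e+00
F9,BAT,1.92e+02,3.56e+01
F9,FA,3.82e+01,1.12e+01
F9,MFO,1.59e+02,3.21e+01
F9,DE,1.58e+02,1.17e+01
F10,GA,1.36e+01,1.51e+00
F10,PSO,1.75e+01,3.67e-01
F10,BBO,2.13e+00,3.53e-01
F10,FPA,7.14e+00,1.08e+00
F10,GWO,1.03e-13,1.70e-14
F10,BAT,1.92e+01,2.43e-01
F10,FA,4.58e-02,1.20e-02
F10,MFO,1.74e+01,4.95e+00
F10,DE,1.21e-02,3.30e-03
F11,GA,1.01e+01,2.43e+00
F11,PSO,1.70e+02,3.17e+01
F11,BBO,1.46e+00,1.69e-01
F11,FPA,1.73e+01,3.63e+00
F11,GWO,4.76e-03,8.57e-03
F11,BAT,6.01e+02,5.50e+01
F11,FA,4.23e-03,1.29e-03
F11,MFO,3.10e+01,5.94e+01
F11,DE,3.52e-02,7.20e-02
F12,GA,4.77e+00,1.56e+00
F12,PSO,1.51e+07,9.88e+06
F12,BBO,6.68e-01,2.62e-01
F12,FPA,3.05e+02,1.04e+03
F12,GWO,4.83e-02,2.12e-02
F12,BAT,4.71e+08,1.54e+08
F12,FA,3.13e-04,1.76e-04
F12,MFO,2.46e+02,1.21e+03
F12,DE,2.25e-03,1.70e-03
F13,GA,1.52e+01,4.52e+00
F13,PSO,5.73e+07,2.68e+07
F13,BBO,1.82e+00,3.41e-01
F13,FPA,9.59e+04,1.46e+05
F13,GWO,5.96e-01,2.23e-01
F13,BAT,9.40e+08,1.67e+08
F13,FA,2.08e-03,9.62e-04
F13,MFO,2.73e+07,1.04e+08
F13,DE,9.12e-03,1.16e-02
F14,GA,9.98e-01,4.52e-16
F14,PSO,1.39e+00,4.60e-01
F14,BBO,9.98e-01,4.52e-16
F14,FPA,9.98e-01,2.00e-04
F14,GWO,4.17e+00,3.61e+00
F14,BAT,1.27e+01,6.96e+00
F14,FA,3.51e+00,2.16e+00
F14,MFO,2.74e+00,1.82e+00
F14,DE,1.23e+00,9.23e-01
F15,GA,3.33e-02,2.70e-02
F15,PSO,1.61e-03,4.60e-04
F15,BBO,1.66e-02,8.60e-03
F15,FPA,6.88e-04,1.55e-04
F15,GWO,6.24e-03,1.25e-02
F15,BAT,3.00e-02,3.33e-02
F15,FA,1.01e-03,4.01e-04
F15,MFO,2.35e-03,4.92e-03
F15,DE,5.63e-04,2.81e-04
F16,GA,-3.78e-01,3.42e-01
F16,PSO,-1.03e+00,2.95e-03
F16,BBO,-8.30e-01,3.16e-01
F16,FPA,-1.03e+00,6.78e-16
F16,GWO,-1.03e+00,6.78e-16
F16,BAT,-6.87e-01,8.18e-01
F16,FA,-1.03e+00,6.78e-16
F16,MFO,-1.03e+00,6.78e-16
F16,DE,-1.03e+00,6.78e-16
F17,GA,5.24e-01,6.06e-02
F17,PSO,4.00e-01,1.39e-03
F17,BBO,5.49e-01,6.05e-02
F17,FPA,3.98e-01,1.69e-16
F17,GWO,3.98e-01,1.69e-16
F17,BAT,3.98e-01,1.58e-03
F17,FA,3.98e-01,1.69e-16
F17,MFO,3.98e-01,1.69e-16
F17,DE,3.98e-01,1.69e-16
F18,GA,3.00e+00,0.00e+00
F18,PSO,3.10e+00,7.60e-02
F18,BBO,3.00e+00,0.00e+00
F18,FPA,3.00e+00,0.00e+00
F18,GWO,3.00e+00,4.07e-05
F18,BAT,1.47e+01,2.21e+01
F18,FA,3.00e+00,0.00e+00
F18,MFO,3.00e+00,0.00e+00
F18,DE,3.00e+00,0.00e+00
F19,GA,-3.42e+00,3.03e-01
F19,PSO,-3.86e+00,1.24e-03
F19,BBO,-3.78e+00,1.26e-01
F19,FPA,-3.86e+00,3.16e-15
F19,GWO,-3.86e+00,3.14e-03
F19,BAT,-3.84e+00,1.41e-01
F19,FA,-3.86e+00,3.16e-15
F19,MFO,-3.86e+00,1.44e-03
F19,DE,-3.86e+00,3.16e-15
F20,GA,-1.61351,0.46049
F20,PSO,-3.11088,0.029126
F20,BBO,-2.70774,0.357832
F20,FPA,-3.2951,0.019514
F20,GWO,-3.25866,0.064305
F20,BAT,-3.2546,0.058943
F20,FA,-3.28105,0.063635
F20,MFO,-3.23509,0.064223
F20,DE,-3.27048,0.058919
F21,GA,-6.66177,3.732521
F21,PSO,-4.14764,0.919578
F21,BBO,-8.31508,2.883867
F21,FPA,-5.21514,0.008154
F21,GWO,-8.64121,2.563356
F21,BAT,-4.2661,2.554009
F21,FA,-7.67362,3.50697
F21,MFO,-6.8859,3.18186
F21,DE,-9.64796,1.51572
F22,GA,-5.58399,2.605837
F22,PSO,-6.01045,1.962628
F22,BBO,-9.38408,2.597238
F22,FPA,-5.34373,0.053685
F22,GWO,-10.4014,0.000678
F22,BAT,-5.60638,3.022612
F22,FA,-9.63827,2.293901
F22,MFO,-8.26492,3.076809
F22,DE,-9.74807,1.987703
F23,GA,-4.69882,3.256702
F23,PSO,-4.72192,1.742618
F23,BBO,-6.2351,3.78462
F23,FPA,-5.29437,0.356377
F23,GWO,-10.0836,1.721889
F23,BAT,-3.97284,3.008279
F23,FA,-9.75489,2.345487
F23,MFO,-7.65923,3.576927
F23,DE,-10.5364,8.88e-15
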