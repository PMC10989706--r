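temperature,lnKeq,sigma
283,-6.39133,0.05
285,-6.1731,0.05
287,-5.81808,0.05
289,-5.53926,0.05
291,-5.28233,0.05
293,-5.09268,0.05
295,-4.72534,0.05
297,-4.46504,0.05
299,-4.13748,0.05
301,-3.89958,0.05
303,-3.63255,0.05
305,-3.38837,0.05
307,-3.10603,0.05
309,-2.85268,0.05
311,-2.71842,0.05
313,-2.27662,0.05
315,-2.06917,0.05
317,-1.84822,0.05
319,-1.66146,0.05
321,-1.35183,0.05
323,-1.17075,0.05
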