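parameter_name,global_mean,global_sd,effect_score
carbohydrate,132.0,20.0,0.097
protein,39.0,8.0,0.021
total_fat,35.0,9.0,0.298
alcohol,6.8,4.0,-0.278
fiber,9.2,2.4,-0.663
cholesterol,136.0,25.0,0.110
saturated_fat,14.0,4.0,0.373
mufa,13.0,3.0,-0.009
pufa,6.8,1.8,-0.337
vitamin_a,480.0,250.0,-0.401
vitamin_b1,0.83,0.32,-0.098
vitamin_b2,0.83,0.38,-0.068
vitamin_b3,12.6,5.7,-0.246
vitamin_b6,0.72,0.36,-0.365
vitamin_b12,2.5,1.3,0.106
vitamin_c,57.0,21.0,-0.424
vitamin_d,3.0,1.1,-0.446
vitamin_e,4.2,0.7,-0.419
folic_acid,133.0,34.0,-0.190
iron,6.5,1.8,0.032
magnesium,151.0,68.0,-0.484
zinc,4.8,1.1,-0.313
anthocyanidins,8.8,10.0,-0.131
flavan3ols,46.6,42.0,-0.415
flavones,0.75,0.35,-0.616
flavonols,8.6,3.3,-0.467
flavanones,5.7,1.9,-0.250
isoflavones,0.58,0.25,-0.593
garlic,2.1,1.4,-0.412
onion,17.5,9.0,-0.301
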