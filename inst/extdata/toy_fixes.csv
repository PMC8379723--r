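individual_id,pair_id,sex,colony_id,timestamp,lat,lon
T1,TP1,male,C1,2016-06-01T00:00:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T00:03:00,51.4540469,3.6900000
T1,TP1,male,C1,2016-06-01T00:06:00,51.4549463,3.6900000
T1,TP1,male,C1,2016-06-01T00:09:00,51.4540469,3.6900000
T1,TP1,male,C1,2016-06-01T00:12:00,51.4540469,3.6900000
T1,TP1,male,C1,2016-06-01T00:15:00,51.4549463,3.6900000
T1,TP1,male,C1,2016-06-01T00:18:00,51.4551711,3.6900000
T1,TP1,male,C1,2016-06-01T00:21:00,51.4553959,3.6900000
T1,TP1,male,C1,2016-06-01T00:24:00,51.4556208,3.6900000
T1,TP1,male,C1,2016-06-01T00:27:00,51.4558456,3.6900000
T1,TP1,male,C1,2016-06-01T00:30:00,51.4560704,3.6900000
T1,TP1,male,C1,2016-06-01T00:33:00,51.4562952,3.6900000
T1,TP1,male,C1,2016-06-01T00:36:00,51.4565201,3.6900000
T1,TP1,male,C1,2016-06-01T00:39:00,51.4567449,3.6900000
T1,TP1,male,C1,2016-06-01T00:42:00,51.4569697,3.6900000
T1,TP1,male,C1,2016-06-01T00:45:00,51.4571946,3.6900000
T1,TP1,male,C1,2016-06-01T00:48:00,51.4574194,3.6900000
T1,TP1,male,C1,2016-06-01T00:51:00,51.4576442,3.6900000
T1,TP1,male,C1,2016-06-01T00:54:00,51.4540469,3.6900000
T1,TP1,male,C1,2016-06-01T00:57:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T01:00:00,51.4949660,3.6900000
T1,TP1,male,C1,2016-06-01T01:03:00,51.5399320,3.6900000
T1,TP1,male,C1,2016-06-01T01:06:00,51.6298641,3.6900000
T1,TP1,male,C1,2016-06-01T05:00:00,51.6298641,3.6900000
T1,TP1,male,C1,2016-06-01T05:03:00,51.5399320,3.6900000
T1,TP1,male,C1,2016-06-01T05:06:00,51.4949660,3.6900000
T1,TP1,male,C1,2016-06-01T05:09:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T05:12:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T05:15:00,51.4634898,3.6900000
T1,TP1,male,C1,2016-06-01T05:18:00,51.4769796,3.6900000
T1,TP1,male,C1,2016-06-01T05:21:00,51.4634898,3.6900000
T1,TP1,male,C1,2016-06-01T05:24:00,51.4580939,3.6900000
T1,TP1,male,C1,2016-06-01T05:27:00,51.4553959,3.6900000
T1,TP1,male,C1,2016-06-01T05:30:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T05:33:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T05:36:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T05:39:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T05:42:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T05:45:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T05:48:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T05:51:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T05:54:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T05:57:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T06:00:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T06:03:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T06:06:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T06:09:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T06:12:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T06:15:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T06:18:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T06:21:00,51.4742816,3.6900000
T1,TP1,male,C1,2016-06-01T06:27:00,51.4724830,3.6900000
T1,TP1,male,C1,2016-06-01T06:30:00,51.4500000,3.6900000
T1,TP1,male,C1,2016-06-01T06:33:00,51.4500000,3.6900000
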