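column_id,timestamp,detector_index
col01,2021-05-31T00:00:05.295,1
col01,2021-05-31T00:00:06.295,2
col01,2021-05-31T00:00:07.295,3
col01,2021-05-31T00:00:08.295,4
col01,2021-05-31T00:00:09.295,5
col01,2021-05-31T00:04:00.128,2
col01,2021-05-31T00:05:50.793,1
col01,2021-05-31T00:05:51.793,2
col01,2021-05-31T00:05:52.793,3
col01,2021-05-31T00:05:53.793,4
col01,2021-05-31T00:05:54.793,5
col01,2021-05-31T00:11:26.401,1
col01,2021-05-31T00:16:37.457,5
col01,2021-05-31T00:22:55.068,1
col01,2021-05-31T00:22:56.068,2
col01,2021-05-31T00:22:57.068,3
col01,2021-05-31T00:22:58.068,4
col01,2021-05-31T00:22:59.068,5
col01,2021-05-31T00:32:33.131,1
col01,2021-05-31T00:32:34.131,2
col01,2021-05-31T00:32:35.131,3
col01,2021-05-31T00:32:36.131,4
col01,2021-05-31T00:32:37.131,5
col01,2021-05-31T00:32:47.096,1
col01,2021-05-31T00:32:48.096,2
col01,2021-05-31T00:32:49.096,3
col01,2021-05-31T00:32:50.096,4
col01,2021-05-31T00:32:51.096,5
col01,2021-05-31T00:38:06.381,1
col01,2021-05-31T00:38:07.381,2
col01,2021-05-31T00:38:08.381,3
col01,2021-05-31T00:38:09.381,4
col01,2021-05-31T00:38:09.765,3
col01,2021-05-31T00:38:10.381,5
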