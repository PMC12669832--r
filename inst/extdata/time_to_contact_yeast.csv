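condition,larva,time
yeast_25,1,02:52
yeast_25,2,09:29
yeast_25,3,01:50
yeast_25,4,00:17
yeast_25,5,06:05
yeast_25,6,03:09
yeast_25,7,01:08
yeast_25,8,02:59
yeast_25,9,02:56
yeast_25,10,05:15
yeast_25,11,00:41
yeast_25,12,09:22
yeast_25,13,00:29
yeast_25,14,05:35
yeast_25,15,02:08
yeast_25,16,02:07
yeast_25,17,01:35
yeast_50,1,04:08
yeast_50,2,00:23
yeast_50,3,14:54
yeast_50,4,14:59
yeast_50,5,12:29
yeast_50,6,01:51
yeast_50,7,02:24
yeast_50,8,03:30
yeast_50,9,08:15
yeast_50,10,01:40
yeast_50,11,09:09
yeast_50,12,03:20
yeast_50,13,13:45
yeast_50,14,10:03
yeast_75,1,00:31
yeast_75,2,01:39
yeast_75,3,03:44
yeast_75,4,06:56
yeast_75,5,04:06
yeast_75,6,03:17
yeast_75,7,02:47
yeast_75,8,06:02
yeast_75,9,03:05
yeast_75,10,05:42
yeast_75,11,12:01
yeast_75,12,02:26
yeast_75,13,00:32
yeast_75,14,11:02
yeast_75,15,05:41
yeast_75,16,02:32
yeast_75,17,00:26
yeast_75,18,01:27
yeast_100,1,09:30
yeast_100,2,04:57
yeast_100,3,04:11
yeast_100,4,04:57
yeast_100,5,00:59
yeast_100,6,01:11
yeast_100,7,12:28
yeast_100,8,00:45
yeast_100,9,01:14
yeast_100,10,00:45
yeast_100,11,07:14
yeast_100,12,11:21
yeast_100,13,09:01
yeast_100,14,03:17
yeast_100,15,00:35
yeast_100,16,01:19
yeast_100,17,01:06
yeast_100,18,01:13
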